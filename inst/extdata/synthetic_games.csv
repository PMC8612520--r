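game_id,group_id,goal_structure,abvd_linked,describable,local_origin,period_start,period_end
game0001,G01,solitary,TRUE,TRUE,TRUE,1888,1915
game0002,G02,solitary,TRUE,TRUE,TRUE,1862,1866
game0003,G02,competitive,TRUE,TRUE,TRUE,1886,1899
game0004,G02,competitive_vs_solitary,TRUE,TRUE,TRUE,1899,1912
game0005,G02,cooperative,TRUE,TRUE,TRUE,1878,1889
game0006,G02,cooperative,TRUE,TRUE,TRUE,1866,1869
game0007,G03,solitary,TRUE,TRUE,TRUE,1886,1894
game0008,G03,cooperative,TRUE,TRUE,TRUE,1871,1880
game0009,G04,solitary,TRUE,TRUE,TRUE,1881,1889
game0010,G04,solitary,TRUE,TRUE,TRUE,1897,1913
game0011,G04,solitary,TRUE,TRUE,TRUE,1869,1879
game0012,G04,competitive,TRUE,TRUE,TRUE,1875,1891
game0013,G04,competitive_vs_solitary,TRUE,TRUE,TRUE,1880,1892
game0014,G04,competitive_vs_solitary,TRUE,TRUE,TRUE,1871,1887
game0015,G04,competitive_vs_solitary,TRUE,TRUE,TRUE,1890,1899
game0016,G04,competitive_vs_solitary,TRUE,TRUE,TRUE,1873,1874
game0017,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1894,1921
game0018,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1892,1913
game0019,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1899,1900
game0020,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1890,1902
game0021,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1884,1909
game0022,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1885,1913
game0023,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1861,1883
game0024,G04,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1895,1921
game0025,G04,cooperative_group_vs_cooperative_group,TRUE,TRUE,TRUE,1889,1899
game0026,G04,cooperative,TRUE,TRUE,TRUE,1880,1909
game0027,G04,cooperative,TRUE,TRUE,TRUE,1892,1906
game0028,G04,cooperative,TRUE,TRUE,TRUE,1882,1908
game0029,G04,cooperative,TRUE,TRUE,TRUE,1880,1899
game0030,G05,solitary,TRUE,TRUE,TRUE,1884,1896
game0031,G05,competitive,TRUE,TRUE,TRUE,1860,1875
game0032,G05,competitive,TRUE,TRUE,TRUE,1900,1915
game0033,G05,competitive_vs_solitary,TRUE,TRUE,TRUE,1868,1889
game0034,G05,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1897,1923
game0035,G05,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1879,1891
game0036,G05,cooperative_group_vs_cooperative_group,TRUE,TRUE,TRUE,1861,1888
game0037,G05,cooperative_group_vs_cooperative_group,TRUE,TRUE,TRUE,1871,1875
game0038,G05,cooperative,TRUE,TRUE,TRUE,1895,1923
game0039,G06,solitary,TRUE,TRUE,TRUE,1893,1901
game0040,G06,solitary,TRUE,TRUE,TRUE,1870,1879
game0041,G06,competitive,TRUE,TRUE,TRUE,1871,1885
game0042,G06,competitive_vs_solitary,TRUE,TRUE,TRUE,1872,1890
game0043,G07,competitive,TRUE,TRUE,TRUE,1860,1877
game0044,G08,solitary,TRUE,TRUE,TRUE,1893,1920
game0045,G08,solitary,TRUE,TRUE,TRUE,1878,1905
game0046,G08,solitary,TRUE,TRUE,TRUE,1880,1910
game0047,G08,competitive,TRUE,TRUE,TRUE,1881,1909
game0048,G08,competitive,TRUE,TRUE,TRUE,1880,1883
game0049,G08,competitive,TRUE,TRUE,TRUE,1862,1870
game0050,G08,competitive,TRUE,TRUE,TRUE,1869,1885
game0051,G08,competitive,TRUE,TRUE,TRUE,1872,1875
game0052,G08,competitive_vs_solitary,TRUE,TRUE,TRUE,1873,1894
game0053,G08,competitive_vs_solitary,TRUE,TRUE,TRUE,1885,1914
game0054,G08,competitive_vs_solitary,TRUE,TRUE,TRUE,1869,1891
game0055,G08,competitive_vs_solitary,TRUE,TRUE,TRUE,1887,1896
game0056,G08,competitive_vs_solitary,TRUE,TRUE,TRUE,1882,1886
game0057,G08,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1887,1891
game0058,G08,competitive_vs_cooperative_group,TRUE,TRUE,TRUE,1872,1876
game0059,G08,cooperative_group_vs_cooperative_group,TRUE,TRUE,TRUE,1896,1920
game0060,G08,cooperative_group_vs_cooperative_group,TRUE,TRUE,TRUE,1886,1899
bad_abvd,G01,competitive,FALSE,TRUE,TRUE,1900,1900
bad_describe,G01,competitive,TRUE,FALSE,TRUE,1900,1900
bad_origin,G01,competitive,TRUE,TRUE,FALSE,1900,1900
bad_tree,not_a_tip,competitive,TRUE,TRUE,TRUE,1900,1900
bad_covariates,G09,competitive,TRUE,TRUE,TRUE,1900,1900
bad_time,G01,competitive,TRUE,TRUE,TRUE,1951,1960
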