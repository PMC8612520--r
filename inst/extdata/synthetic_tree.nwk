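(((G03:0.02911613899,(G09:0.02393177632,G02:0.02393177632):0.005184362666):0.04871070305,G06:0.07782684204):0.922173158,((G08:0.3474191586,G01:0.3474191586):0.4514937888,(G05:0.362932477,(G07:0.3212115616,G04:0.3212115616):0.04172091539):0.4359804704):0.2010870526);
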