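reader,pom_DM,pom_AICAD_SM,pom_DM_DBT,pom_AICAD_SM_DBT,birads_DM,birads_AICAD_SM,birads_DM_DBT,birads_AICAD_SM_DBT
R1,0.863,0.912,0.892,0.917,0.857,0.908,0.892,0.916
R2,0.899,0.902,0.922,0.908,0.882,0.890,0.913,0.892
R3,0.843,0.913,0.890,0.925,0.834,0.910,0.884,0.922
R4,0.878,0.881,0.874,0.886,0.870,0.877,0.864,0.883
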