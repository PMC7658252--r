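label,attach_class,smarts,removal_smirks,note
Boc,amine,[#7X3:1][CX3](=[OX1])[OX2][CX4]([CH3])([CH3])[CH3],[#7X3:1][CX3](=[OX1])[OX2][CX4]([CH3])([CH3])[CH3]>>[#7X3:1],tert-butyl carbamate on nitrogen
Fmoc,amine,[#7X3:1][CX3](=[OX1])[OX2][CH2][CH1]1c2ccccc2-c2ccccc21,[#7X3:1][CX3](=[OX1])[OX2][CH2][CH1]1c2ccccc2-c2ccccc21>>[#7X3:1],fluorenylmethyloxycarbonyl on nitrogen
Cbz,amine,[#7X3:1][CX3](=[OX1])[OX2][CH2]c1ccccc1,[#7X3:1][CX3](=[OX1])[OX2][CH2]c1ccccc1>>[#7X3:1],benzyloxycarbonyl on nitrogen
tBu_ester,carboxyl,[#6:9][CX3:1](=[OX1:2])[OX2:3][CX4]([CH3])([CH3])[CH3],[#6:9][CX3:1](=[OX1:2])[OX2:3][CX4]([CH3])([CH3])[CH3]>>[#6:9][CX3:1](=[OX1:2])[OX2H1:3],tert-butyl ester of a carboxylic acid; carbon anchor excludes carbamates
Bn_ester,carboxyl,[#6:9][CX3:1](=[OX1:2])[OX2:3][CH2]c1ccccc1,[#6:9][CX3:1](=[OX1:2])[OX2:3][CH2]c1ccccc1>>[#6:9][CX3:1](=[OX1:2])[OX2H1:3],benzyl ester of a carboxylic acid
tBu_ether,hydroxyl,[#6;!$([CX3]=[OX1]):1][OX2:2][CX4]([CH3])([CH3])[CH3],[#6;!$([CX3]=[OX1]):1][OX2:2][CX4]([CH3])([CH3])[CH3]>>[#6:1][OX2H1:2],tert-butyl ether of an alcohol; anchor atom must not be an acyl carbon
benzoate,hydroxyl,[#6;!$([CX3]=[OX1]):1][OX2:2][CX3](=[OX1])c1ccccc1,[#6;!$([CX3]=[OX1]):1][OX2:2][CX3](=[OX1])c1ccccc1>>[#6:1][OX2H1:2],benzoyl ester masking a hydroxyl; distinguished from Bn_ester by the attachment side
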