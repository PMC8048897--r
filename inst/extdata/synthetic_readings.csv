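section_id,angle_deg,reading_cm,scheme
deep_fissured,59.57899228669703,1.8148703823246668,random
deep_fissured,321.0481010377407,2.111077390910731,random
deep_fissured,91.77677689120173,0.7232976167900782,random
deep_fissured,270.34827251918614,0.7375456906534552,random
deep_fissured,290.7073089759797,2.0731353753622006,random
deep_fissured,268.06325951591134,1.182785263516353,random
deep_fissured,37.8294625505805,3.1,random
deep_fissured,23.80588416941464,1.1599202397336283,random
deep_fissured,238.21138470433652,1.0658283822264805,random
deep_fissured,355.0566936470568,0.9190124125225836,random
deep_fissured,260.8119868207723,2.5957109461575705,random
deep_fissured,347.3468053713441,2.485234215470711,random
deep_fissured,326.0027769394219,1.3636100552989245,random
deep_fissured,128.69868585839868,2.3276539474426037,random
deep_fissured,27.765947682783008,1.8663095746960878,random
deep_fissured,314.53504879027605,3.093642932374507,random
deep_fissured,85.91406896710396,1.584032839744436,random
deep_fissured,170.7177177350968,3.1,random
deep_fissured,324.8446038644761,1.538333197576169,random
deep_fissured,253.34778478369117,3.079687347537814,random
deep_fissured,107.69883370958269,2.897811191454813,random
deep_fissured,53.56910048983991,0.7343159888172788,random
deep_fissured,123.59718885272741,1.3502837683561986,random
deep_fissured,292.5689207017422,1.7158179707929566,random
deep_fissured,343.94808017648757,3.1,random
deep_fissured,237.61251725256443,1.1950909024236192,random
deep_fissured,176.50733152404428,2.396564210155817,random
deep_fissured,252.29117120616138,2.851622633882291,random
deep_fissured,324.1059193946421,1.6497718715643643,random
deep_fissured,306.1486140266061,1.7977638145670505,random
deep_fissured,50.83424557931721,0.951103585998005,random
deep_fissured,169.88660467788577,3.1,random
deep_fissured,115.33965258859098,1.4339450933582834,random
deep_fissured,195.7576909661293,2.6195287793846376,random
deep_fissured,33.14708299934864,2.8261872596826554,random
deep_fissured,303.61355845816433,1.311185725474167,random
deep_fissured,119.23241562210023,0.6881501827717869,random
deep_fissured,46.089679850265384,1.804157437398888,random
deep_fissured,256.2949262280017,3.1,random
deep_fissured,281.3344242889434,2.6323288344702003,random
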