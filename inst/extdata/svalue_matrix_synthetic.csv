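# Synthetic S-value matrix, mGy/(MBq*h), 70-kg adult stand-in.
# Generated by petdosim::synthetic_svalue_matrix(); NOT a published phantom.
target,brain,stomach,heart_contents,kidneys,lungs,thyroid,urinary_bladder_contents,spleen,red_marrow,remainder
adrenals,0.00480856023984212,0.0387003965894632,0.00577186135387048,0.0504926369133475,0.00577186135387048,0.0049127857081796,0.00557975875067855,0.0440378579431411,0.016658247005111,0.00475904940725211
brain,0.1617442210154,0.00485241452200446,0.00577186135387048,0.00480856023984212,0.00577186135387048,0.0149147737789815,0.00476280943034047,0.00485241452200446,0.0049127857081796,0.00475904940725211
breasts,0.00542821702385596,0.00906228287987189,0.0195350530037966,0.00633531240440664,0.0157968800796323,0.00804397485361816,0.00481690195030691,0.00906228287987189,0.0106929471763158,0.00475904940725211
gallbladder_wall,0.00482677341451223,0.0493027256692412,0.00633531240440664,0.0455007336497051,0.00633531240440664,0.00497632376694517,0.00530769242436587,0.0541754038607488,0.0199806764077937,0.00475904940725211
lli_wall,0.00476648752132323,0.00577186135387048,0.00485241452200446,0.0073018308578015,0.00485241452200446,0.00477915812876038,0.0236860780082189,0.00577186135387048,0.00530769242436587,0.00475904940725211
small_intestine,0.00477915812876038,0.010490605539109,0.00507009021033873,0.0138985398428479,0.00507009021033873,0.00481690195030691,0.00804397485361816,0.010490605539109,0.0073018308578015,0.00475904940725211
stomach_wall,0.00485241452200446,0.383754883116777,0.0073018308578015,0.0228759362499997,0.0073018308578015,0.00507009021033873,0.00513326333318103,0.0364229686136315,0.0164545537056347,0.00475904940725211
uli_wall,0.00477410234691412,0.00804397485361816,0.00497632376694517,0.015610233128034,0.00497632376694517,0.00480149471675786,0.010490605539109,0.00804397485361816,0.00633531240440664,0.00475904940725211
heart_wall,0.00577186135387048,0.0073018308578015,0.223319337189247,0.00577186135387048,0.018522242119623,0.010490605539109,0.00480149471675786,0.0073018308578015,0.00979555866720956,0.00475904940725211
kidneys,0.00480856023984212,0.0204687696845735,0.00577186135387048,0.65199083783501,0.00577186135387048,0.0049127857081796,0.00557975875067855,0.0220896348254495,0.0115747867414748,0.00475904940725211
liver,0.00485241452200446,0.0158742275665239,0.0073018308578015,0.0120259478226841,0.00698308565484438,0.00507009021033873,0.00513326333318103,0.0166522059260402,0.0103729895151764,0.00475904940725211
lungs,0.00577186135387048,0.0073018308578015,0.0171948821245771,0.00577186135387048,0.220457753199746,0.010490605539109,0.00480149471675786,0.0073018308578015,0.00834312664799738,0.00475904940725211
muscle,0.0049127857081796,0.00692839666455393,0.00578766221820785,0.00620593327208019,0.00567309788733961,0.00527918300695104,0.00497632376694517,0.00700393938925922,0.0071013738653809,0.00475904940725211
ovaries,0.0047646972402921,0.00542821702385596,0.00482677341451223,0.00633531240440664,0.00482677341451223,0.00477410234691412,0.0496520292335505,0.00542821702385596,0.00513326333318103,0.00475904940725211
pancreas,0.00482677341451223,0.0320221385048155,0.00633531240440664,0.0301755534512739,0.00633531240440664,0.00497632376694517,0.00530769242436587,0.0354396153212262,0.01554734602656,0.00475904940725211
red_marrow,0.0049127857081796,0.0152354699555858,0.0093199155451594,0.0115747867414748,0.00834312664799738,0.00530769242436587,0.00497632376694517,0.0160628198852701,0.199409865198802,0.00475904940725211
osteogenic_cells,0.0049127857081796,0.027875849555844,0.010490605539109,0.0194725032202651,0.010490605539109,0.00530769242436587,0.00497632376694517,0.0306666312579021,0.0213377383927189,0.00475904940725211
skin,0.0049127857081796,0.0115402393668868,0.00780176761759956,0.00921013344650501,0.00725277747552675,0.00530769242436587,0.00497632376694517,0.011966217116126,0.011071460473751,0.00475904940725211
spleen,0.00485241452200446,0.0318749284362319,0.0073018308578015,0.0220896348254495,0.0073018308578015,0.00507009021033873,0.00513326333318103,1.02136820403017,0.0160628198852701,0.00475904940725211
testes,0.00476098576740202,0.0049127857081796,0.00477915812876038,0.00507009021033873,0.00477915812876038,0.00476397707855552,0.0329373164688716,0.0049127857081796,0.00485241452200446,0.00475904940725211
thymus,0.00804397485361816,0.00557975875067855,0.0268409328571847,0.00513326333318103,0.0195545675671899,0.0418095340049547,0.00477915812876038,0.00557975875067855,0.00633531240440664,0.00475904940725211
thyroid,0.0149147737789815,0.00507009021033873,0.010490605539109,0.0049127857081796,0.010490605539109,7.86749063807514,0.00476888086830872,0.00507009021033873,0.00530769242436587,0.00475904940725211
urinary_bladder_wall,0.00476280943034047,0.00513326333318103,0.00480149471675786,0.00557975875067855,0.00480149471675786,0.00476888086830872,0.47069305656585,0.00513326333318103,0.00497632376694517,0.00475904940725211
uterus,0.00476397707855552,0.00530769242436587,0.00481690195030691,0.00601762400832433,0.00481690195030691,0.00477209580816585,0.0359879601733079,0.00530769242436587,0.00507009021033873,0.00475904940725211
total_body,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211,0.00475904940725211
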