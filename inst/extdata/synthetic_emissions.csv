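publication_id,n_rate_kg_ha,n2o_kg_n_ha_yr,replicate,land_use,soil_class,gas_measured,inhibitor,grazing,continent
pub001,0,5.811965776030014,1,agricultural,mineral,N2O,0,0,Europe
pub001,0,4.943442554623348,2,agricultural,mineral,N2O,0,0,Europe
pub001,141.25101176524865,1.8728686400369394,1,agricultural,mineral,N2O,0,0,Europe
pub001,141.25101176524865,0.3921367293409559,2,agricultural,mineral,N2O,0,0,Europe
pub001,215.19715383523422,3.0582543102400086,1,agricultural,mineral,N2O,0,0,Europe
pub001,215.19715383523422,7.247000964570905,2,agricultural,mineral,N2O,0,0,Europe
pub002,0,0.9634908438002692,1,agricultural,mineral,N2O,0,0,Europe
pub002,0,1.6146075665779769,2,agricultural,mineral,N2O,0,0,Europe
pub002,61.19666857009907,-0.6743197540506343,1,agricultural,mineral,N2O,0,0,Europe
pub002,61.19666857009907,-2.079044305830548,2,agricultural,mineral,N2O,0,0,Europe
pub002,161.55495821036058,2.230425413009586,1,agricultural,mineral,N2O,0,0,Europe
pub002,161.55495821036058,0.4360978475075392,2,agricultural,mineral,N2O,0,0,Europe
pub003,0,2.3415377752281916,1,agricultural,mineral,N2O,0,0,Europe
pub003,0,4.408643076018447,2,agricultural,mineral,N2O,0,0,Europe
pub003,111.36791446871025,8.277401690204943,1,agricultural,mineral,N2O,0,0,Europe
pub003,111.36791446871025,8.277370629809282,2,agricultural,mineral,N2O,0,0,Europe
pub003,412.4601003247661,21.695954604707936,1,agricultural,mineral,N2O,0,0,Europe
pub003,412.4601003247661,18.965303017627388,2,agricultural,mineral,N2O,0,0,Europe
pub004,0,2.596164061662041,1,agricultural,mineral,N2O,0,0,Europe
pub004,0,0.40328046711459825,2,agricultural,mineral,N2O,0,0,Europe
pub004,76.53283513019751,0.9667178871280975,1,agricultural,mineral,N2O,0,0,Europe
pub004,76.53283513019751,3.1877600903191556,2,agricultural,mineral,N2O,0,0,Europe
pub004,168.64467017808298,2.2287600047142364,1,agricultural,mineral,N2O,0,0,Europe
pub004,168.64467017808298,0.9205201561944412,2,agricultural,mineral,N2O,0,0,Europe
pub005,0,3.455607584196585,1,agricultural,mineral,N2O,0,0,Europe
pub005,0,0.08500197393999243,2,agricultural,mineral,N2O,0,0,Europe
pub005,30.57762766585452,-0.6516692385191847,1,agricultural,mineral,N2O,0,0,Europe
pub005,30.57762766585452,1.6321041481308702,2,agricultural,mineral,N2O,0,0,Europe
pub005,0,0.990663819098099,1,agricultural,mineral,N2O,0,0,Europe
pub005,0,0.7420476814129338,2,agricultural,mineral,N2O,0,0,Europe
pub006,0,1.0757873627322425,1,agricultural,mineral,N2O,0,0,Europe
pub006,0,0.1261434147039675,2,agricultural,mineral,N2O,0,0,Europe
pub006,110.06874996989804,6.26207637452731,1,agricultural,mineral,N2O,0,0,Europe
pub006,110.06874996989804,0.7184677564961794,2,agricultural,mineral,N2O,0,0,Europe
pub006,42.222945975547944,4.7103374635956685,1,agricultural,mineral,N2O,0,0,Europe
pub006,42.222945975547944,0.3746817950978172,2,agricultural,mineral,N2O,0,0,Europe
pub007,0,1.9142157616874962,1,agricultural,mineral,N2O,0,0,Europe
pub007,0,-2.4049827029002593,2,agricultural,mineral,N2O,0,0,Europe
pub007,143.6915188422274,1.4202896536823844,1,agricultural,mineral,N2O,0,0,Europe
pub007,143.6915188422274,-1.1323657993470657,2,agricultural,mineral,N2O,0,0,Europe
pub007,71.87106923201189,2.0735307819611166,1,agricultural,mineral,N2O,0,0,Europe
pub007,71.87106923201189,-1.1755895689450355,2,agricultural,mineral,N2O,0,0,Europe
pub008,0,2.822179252629059,1,agricultural,mineral,N2O,0,0,Europe
pub008,0,1.4006056360859325,2,agricultural,mineral,N2O,0,0,Europe
pub008,400.5215517276709,1.5447044132573104,1,agricultural,mineral,N2O,0,0,Europe
pub008,400.5215517276709,0.93319727030689,2,agricultural,mineral,N2O,0,0,Europe
pub008,53.71724815655119,-1.8953770503839042,1,agricultural,mineral,N2O,0,0,Europe
pub008,53.71724815655119,0.686626914107945,2,agricultural,mineral,N2O,0,0,Europe
pub901,0,5.811965776030014,1,natural,mineral,N2O,0,0,Europe
pub902,0,4.943442554623348,2,agricultural,mineral,NO,0,0,Europe
pub903,141.25101176524865,1.8728686400369394,1,agricultural,organic,N2O,0,0,Europe
pub904,620,0.3921367293409559,2,agricultural,mineral,N2O,0,0,Europe
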