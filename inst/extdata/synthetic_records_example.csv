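study_id,mouse_id,strain,day,operator_id,instrument,length,width,height,area,weight,excluded
synthetic,m001,Nude,0,op01,calliper,11.6068057194009,10.8010672684734,NA,NA,NA,FALSE
synthetic,m001,Nude,0,op02,calliper,10.5824251125938,10.521044797511,NA,NA,NA,FALSE
synthetic,m001,Nude,0,op03,calliper,10.2816390638566,9.73167118154509,NA,NA,NA,FALSE
synthetic,m001,Nude,3,op01,calliper,12.6042992568227,9.7017033130126,NA,NA,0.646927159306802,FALSE
synthetic,m001,Nude,3,op02,calliper,10.5787802272964,9.77066604044802,NA,NA,0.646927159306802,FALSE
synthetic,m001,Nude,3,op03,calliper,11.9849493006893,10.7253505301492,NA,NA,0.646927159306802,FALSE
synthetic,m002,NSG,0,op01,calliper,11.1171790696763,8.85842030892661,NA,NA,NA,FALSE
synthetic,m002,NSG,0,op02,calliper,8.63574942798504,8.19594957376258,NA,NA,NA,FALSE
synthetic,m002,NSG,0,op03,calliper,8.90272312643576,7.56779638309275,NA,NA,NA,FALSE
synthetic,m002,NSG,3,op01,calliper,11.1857676825928,9.54022853349622,NA,NA,0.483614591418309,FALSE
synthetic,m002,NSG,3,op02,calliper,8.80862795332864,8.42840077988895,NA,NA,0.483614591418309,FALSE
synthetic,m003,BALB/c,0,op01,calliper,7.55443268363378,5.98160519293232,NA,NA,NA,FALSE
synthetic,m003,BALB/c,0,op02,calliper,6.02710151250623,5.96533942530854,NA,NA,NA,FALSE
synthetic,m003,BALB/c,0,op03,calliper,7.46247556664647,6.52465684423357,NA,NA,NA,FALSE
synthetic,m003,BALB/c,3,op01,calliper,8.34300013781249,6.11005514448757,NA,NA,0.191821179719197,FALSE
synthetic,m003,BALB/c,3,op02,calliper,6.76249522527167,6.75947279618746,NA,NA,0.191821179719197,FALSE
synthetic,m003,BALB/c,3,op03,calliper,9.5467133899227,6.80707768794029,NA,NA,0.191821179719197,FALSE
synthetic,m004,BALB/c,0,op01,calliper,9.329099617009,7.62446766992874,NA,NA,NA,FALSE
synthetic,m004,BALB/c,0,op02,calliper,10.5177907776417,7.43858870522253,NA,NA,NA,FALSE
synthetic,m004,BALB/c,0,op03,calliper,10.0823639276863,9.9459990151027,NA,NA,NA,FALSE
synthetic,m004,BALB/c,3,op01,calliper,11.1944730872102,8.44270250168449,NA,NA,0.467329557653897,FALSE
synthetic,m004,BALB/c,3,op02,calliper,9.11222685916378,8.31852112229936,NA,NA,0.467329557653897,FALSE
synthetic,m004,BALB/c,3,op03,calliper,12.0493206242175,8.22339182491626,NA,NA,0.467329557653897,FALSE
synthetic,m005,Nude,0,op01,calliper,11.3115134002109,7.84715676917003,NA,NA,NA,FALSE
synthetic,m005,Nude,0,op02,calliper,10.557534376309,7.48241560691768,NA,NA,NA,FALSE
synthetic,m005,Nude,0,op03,calliper,9.62808865883312,7.020424105164,NA,NA,NA,FALSE
synthetic,m005,Nude,3,op01,calliper,14.267953366268,8.49045855908811,NA,NA,0.405267347599588,FALSE
synthetic,m005,Nude,3,op02,calliper,10.6392322619244,7.73091682017653,NA,NA,0.405267347599588,FALSE
synthetic,m005,Nude,3,op03,calliper,11.3940442857847,8.20617865143535,NA,NA,0.405267347599588,FALSE
synthetic,m006,NSG,0,op01,calliper,13.6482873264524,9.63662490865698,NA,NA,NA,FALSE
synthetic,m006,NSG,0,op02,calliper,12.6195728575859,9.64031242726798,NA,NA,NA,FALSE
synthetic,m006,NSG,0,op03,calliper,12.4933265770932,8.94729245556889,NA,NA,NA,FALSE
synthetic,m006,NSG,3,op01,calliper,12.4149209922651,9.66874818866233,NA,NA,0.714358772814544,FALSE
synthetic,m006,NSG,3,op02,calliper,14.0089205228394,10.4372788637582,NA,NA,0.714358772814544,FALSE
synthetic,m006,NSG,3,op03,calliper,13.5871741663844,11.8181346495491,NA,NA,0.714358772814544,FALSE
synthetic,m007,Nude,0,op01,calliper,11.8423211053184,9.0473044824153,NA,NA,NA,FALSE
synthetic,m007,Nude,0,op02,calliper,10.3299990756679,8.13839576346665,NA,NA,NA,FALSE
synthetic,m007,Nude,0,op03,calliper,9.31331822997637,8.00336650801262,NA,NA,NA,FALSE
synthetic,m007,Nude,3,op01,calliper,10.7524150687721,10.3551262318702,NA,NA,0.532569075011395,FALSE
synthetic,m007,Nude,3,op02,calliper,10.6099806013926,7.93424059806029,NA,NA,0.532569075011395,FALSE
synthetic,m007,Nude,3,op03,calliper,13.7345664935121,9.41885091131168,NA,NA,0.532569075011395,FALSE
synthetic,m008,Nude,0,op01,calliper,8.80972059216971,8.37841859409381,NA,NA,NA,FALSE
synthetic,m008,Nude,0,op02,calliper,9.80553942186601,7.81596341951258,NA,NA,NA,FALSE
synthetic,m008,Nude,0,op03,calliper,9.35971409277063,8.17494719417503,NA,NA,NA,FALSE
synthetic,m008,Nude,3,op01,calliper,10.9160917700062,9.09400649093825,NA,NA,0.550320450731784,FALSE
synthetic,m008,Nude,3,op02,calliper,11.0264957974195,9.28420974975068,NA,NA,0.550320450731784,FALSE
synthetic,m008,Nude,3,op03,calliper,10.3368772158667,9.62465224312686,NA,NA,0.550320450731784,FALSE
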