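subject,start_time_h,phase,volume_ml,ohdg_ng_per_ml,creatinine_mg_per_ml
subject2_like,0,day,787.78592984118814,14.216326213695508,0.87844271095355075
subject2_like,12,night,505.39418836438853,15.517292984104257,1.1702801181338334
subject2_like,24,day,746.58423779972748,15.833267707609885,0.81342343297343533
subject2_like,36,night,544.60598745841833,19.731698037101953,1.2766027377416342
subject2_like,48,day,645.85592844450719,25.314216358781252,0.92422122237710291
subject2_like,60,night,508.48218987711925,21.492165200138551,1.2152308805363845
subject2_like,72,day,838.78116224415817,23.597029815580726,1.0326291949466866
subject2_like,84,night,555.1382191133165,12.526683488373157,1.3397687160351688
subject2_like,96,day,887.83785957705857,8.6979860616982094,0.9366215285679319
subject2_like,108,night,542.84269588133088,14.213683627729838,1.3000265282209413
subject2_like,120,day,591.97708877725506,18.473073559740868,0.93960234887367378
subject2_like,132,night,511.27011807348987,15.457657173098928,1.4115873912924806
subject2_like,144,day,712.43554992201291,21.783875499660173,0.88884301982941383
subject2_like,156,night,518.67239594058105,16.91351485516811,1.4592382642796486
subject2_like,168,day,791.35659002101704,15.140602736285041,0.88268448182321979
subject2_like,180,night,442.59373182321184,20.616376823508105,1.401457721141669
subject2_like,192,day,454.76634364173418,23.010736660972643,0.88164407316045146
subject2_like,204,night,510.38816078096738,12.359929500722117,1.2363031459886011
subject2_like,216,day,641.03764377173297,19.96916912952992,0.85821173443615995
subject2_like,228,night,514.62187196389129,20.627291859940399,1.2386584408402215
subject2_like,240,day,499.5335723308084,25.284924287455137,1.0407137800579451
subject2_like,252,night,490.05960108361171,28.210998637483282,1.1902073405352518
subject2_like,264,day,768.4292890002198,18.477422949018919,0.97028595809882368
subject2_like,276,night,488.72545689786176,20.456460832682644,1.1042495983199527
subject2_like,288,day,609.78739587916175,18.355303371283142,1.0255792188928632
subject2_like,300,night,563.14014746877479,20.014613304997539,1.2055433378922336
subject2_like,312,day,647.26247130526474,26.768107533430513,1.0149888192761294
subject2_like,324,night,720.46592814401777,20.986723362035292,1.0924897619227296
subject2_like,336,day,828.75623630388702,17.402060379207274,0.77416313033408757
subject2_like,348,night,412.66283701262927,23.734310924442532,1.3227660647809181
subject2_like,360,day,628.89216130237935,19.695166687177153,0.91023488287735876
subject2_like,372,night,433.91760208743477,16.856723007536171,1.2048790279583173
subject2_like,384,day,709.99889159699353,11.637973003998873,0.84446198147328755
subject2_like,396,night,436.60600688587033,21.860502625283516,1.3545633909382946
subject2_like,408,day,725.38000286142676,23.717168152877321,0.84880670409048842
subject2_like,420,night,438.71963304996785,19.402688928062524,1.3291635309174581
subject2_like,432,day,688.71841542685286,18.984841640654711,0.81999757500854897
subject2_like,444,night,469.75351370739509,19.397415282145847,1.5761442752794952
subject2_like,456,day,665.81191552548898,18.363815062362018,0.87896472879632093
subject2_like,468,night,564.50558010378847,19.449398317665999,1.0814118195148779
subject2_like,480,day,724.51477711993675,16.80530676546795,0.77220608922781231
subject2_like,492,night,596.5981098145769,15.408040850793121,1.201360435078592
subject2_like,504,day,756.19487243167657,28.443709750972204,0.7828857488825306
subject2_like,516,night,532.86635031450101,21.102492160146429,1.3242001837288098
subject2_like,528,day,683.27284523177138,19.132189101338724,0.86035458154434941
subject2_like,540,night,359.78937921770193,27.314445677863358,1.3307563609863799
subject2_like,552,day,684.65123120699548,13.993384682605939,0.90442706752359714
subject2_like,564,night,561.28837751375238,11.483378581155229,1.4015542273277612
subject2_like,576,day,475.76446322678231,27.774189675739869,0.90362173323684702
subject2_like,588,night,508.72310594131034,17.204900494845347,1.4006519374323978
subject2_like,600,day,641.4800495406414,21.05181717921073,0.94762311891820394
subject2_like,612,night,561.81499965170758,10.933991940711712,1.4874330474701958
subject2_like,624,day,650.55283018502644,17.291443154949459,0.84515741936459909
subject2_like,636,night,608.57337190078761,12.767027457054812,1.3682821556628117
subject2_like,648,day,778.40728935885431,10.803975525909186,0.89719233925071429
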