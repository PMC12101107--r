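subject,start_time_h,phase,volume_ml,ohdg_ng_per_ml,creatinine_mg_per_ml
subject1_like,0,day,556.36529558045765,23.524021324729414,0.96626177331682328
subject1_like,12,night,403.51596509054275,17.304552730576276,1.2735658189885952
subject1_like,24,day,617.61769530904621,22.009596685588466,0.93626930194130176
subject1_like,36,night,510.5103684054755,20.004269479330251,1.4643981627017304
subject1_like,48,day,638.3284893016521,35.028697759001354,0.90863412128200427
subject1_like,60,night,524.23923218962204,29.206569653504832,1.4115468879162762
subject1_like,72,day,600.8087182818856,26.673329106410204,0.97558749982883508
subject1_like,84,night,439.16062944303241,30.791316887478715,1.3626671448650454
subject1_like,96,day,497.94182098297898,29.130812065632487,0.8876412636231199
subject1_like,108,night,448.91069205275375,23.942386195397582,1.4033703988033788
subject1_like,120,day,601.65092923544887,20.413813142960311,0.92020624166016274
subject1_like,132,night,373.58569682387446,32.631347451774303,1.2971567426719233
subject1_like,144,day,658.96910715386889,25.582419582187605,0.98207082620008446
subject1_like,156,night,570.81008925724302,23.85338080830811,1.1821921308223184
subject1_like,168,day,984.61439847613883,20.580462616782903,0.8672109278079595
subject1_like,180,night,499.01114175391018,19.877868222366864,1.5866930453753709
subject1_like,192,day,765.13075778573341,13.174984556702974,0.89885780986119268
subject1_like,204,night,533.49591643650285,16.747013628915294,1.3912112292072258
subject1_like,216,day,665.09415885799501,22.806644696836361,1.0887116755214421
subject1_like,228,night,327.15131229125711,53.568678048741972,1.4312937993725487
subject1_like,240,day,655.5423371249168,25.824116971154588,0.81929104857149471
subject1_like,252,night,447.15900458066369,34.898383802205259,1.1712220670317075
subject1_like,264,day,688.50870018724527,20.420672285707905,0.74643607151220526
subject1_like,276,night,404.30246952368969,23.212573462203771,1.3701998952005856
subject1_like,288,day,542.61376552541344,23.155888502366604,0.811469503663522
subject1_like,300,night,565.69598667376897,18.993116606533977,1.6641533822326358
subject1_like,312,day,665.905572869867,25.101029365511234,1.0542215113498847
subject1_like,324,night,507.20544816819466,29.552448111172655,1.452069614501649
subject1_like,336,day,1056.8105676891264,19.123117033078948,0.89466587565366462
subject1_like,348,night,439.61682475706965,33.033892561883526,1.476202837748243
subject1_like,360,day,714.66049605715489,28.769613532429954,0.85297938160245224
subject1_like,372,night,477.18555700277011,19.551057591122277,1.3253757909217476
subject1_like,384,day,830.4624836375109,13.076785662847904,0.93442619039620589
subject1_like,396,night,452.40646177662308,20.123408657719164,1.4874544561156229
subject1_like,408,day,873.46062460663916,21.301352342065798,0.78006390256300595
subject1_like,420,night,378.56936181677207,52.185206954489168,1.1790837075892462
subject1_like,432,day,696.13159981160959,32.690051714009144,0.87831541517110123
subject1_like,444,night,529.24941461903586,29.002077243681587,1.6102174906220257
subject1_like,456,day,558.62340207237457,23.245072175622994,0.84645686732195324
subject1_like,468,night,439.531318121982,16.72858831899222,1.2810180451962185
subject1_like,480,day,714.11258251359482,20.938575987435048,0.87067897077842227
subject1_like,492,night,424.36929690910529,19.225272450590875,1.3400028914077295
subject1_like,504,day,685.10025215322423,29.278813577776408,0.98120387080998916
subject1_like,516,night,462.75077531984158,32.349888467797442,1.2725938807082295
subject1_like,528,day,656.77251634243157,29.623678307775343,0.85477325942161675
subject1_like,540,night,539.08098666923286,20.07608387841605,1.3446320020941167
subject1_like,552,day,766.47469139882026,17.77823224683722,0.81261647459070752
subject1_like,564,night,470.10361123904647,18.616989224314544,1.336190926191543
subject1_like,576,day,732.31321716123148,19.017101407306203,0.78780343473906067
subject1_like,588,night,509.59176613735104,35.602739322736156,1.5986626728919546
subject1_like,600,day,667.7138548868453,32.07223103568127,0.92357392772227753
subject1_like,612,night,401.06414846424451,36.110913906040423,1.2334362909140106
subject1_like,624,day,707.56023962465952,18.323462819457053,0.88867437210561839
subject1_like,636,night,550.63255353949694,23.151322613032956,1.2311443924259824
subject1_like,648,day,859.38065543632206,12.730673389826816,1.0385172980144552
subject1_like,660,night,528.76679055270858,14.649341358823747,1.2636121261167856
subject1_like,672,day,573.31203699596381,26.798568608129418,1.0028238583796871
subject1_like,684,night,567.56001021715895,27.285035400349891,1.2233917023224652
subject1_like,696,day,705.04432335159595,35.25575397056727,0.87812027680979809
subject1_like,708,night,426.46241257686455,35.056554107776449,1.2409291575826176
subject1_like,720,day,849.09591836257107,20.815777248088065,0.97476909723512239
subject1_like,732,night,476.56605808367198,19.893508491888586,1.4688336674919598
subject1_like,744,day,649.64940712675559,19.596705661897261,1.0924904478946433
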