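alpha,beta,x,value
0.3,0.3,0.001,0.333602182282472266
0.3,0.3,0.0031622776601683793,0.332158590849715205
0.3,0.3,0.01,0.327650202764812173
0.3,0.3,0.031622776601683793,0.313940333773842912
0.3,0.3,0.1,0.275493900395358219
0.3,0.3,0.31622776601683793,0.189702473719255209
0.3,0.3,1.0,0.0773167990300896729
0.3,0.3,3.1622776601683793,0.0158342043129582238
0.3,0.3,10.0,0.00205178630322761502
0.3,0.3,31.622776601683793,0.000222661875567056132
0.3,0.3,100.0,0.0000228419672142895102
0.3,0.3,316.22776601683793,2.30260528883668642e-6
0.3,0.3,1000.0,2.30844555448505754e-7
0.3,1.0,0.001,0.998886875627559486
0.3,1.0,0.0031622776601683793,0.996487614767361963
0.3,1.0,0.01,0.988968461657203177
0.3,1.0,0.031622776601683793,0.965851737511253068
0.3,1.0,0.1,0.898811536502722553
0.3,1.0,0.31622776601683793,0.733860289410455512
0.3,1.0,1.0,0.456594408329690671
0.3,1.0,3.1622776601683793,0.202864431665673836
0.3,1.0,10.0,0.0726497290727720862
0.3,1.0,31.622776601683793,0.0239143181529188981
0.3,1.0,100.0,0.00765885622228664149
0.3,1.0,316.22776601683793,0.00243166063119546757
0.3,1.0,1000.0,0.000769932464952577693
0.5,0.5,0.001,0.563190710927675136
0.5,0.5,0.0031622776601683793,0.561038558131549725
0.5,0.5,0.01,0.554301428937292862
0.5,0.5,0.031622776601683793,0.533664300073671407
0.5,0.5,0.1,0.474543885550843623
0.5,0.5,0.31622776601683793,0.335373990410027932
0.5,0.5,1.0,0.136606007391949283
0.5,0.5,3.1622776601683793,0.0247754755630385992
0.5,0.5,10.0,0.00277965610953042837
0.5,0.5,31.622776601683793,0.000281672703755762514
0.5,0.5,100.0,0.0000282052488129965924
0.5,0.5,316.22776601683793,2.8209056045778338e-6
0.5,0.5,1000.0,2.82094368632748334e-7
0.5,1.0,0.001,0.998872620081151409
0.5,1.0,0.0031622776601683793,0.996441728029277922
0.5,1.0,0.01,0.988815461046342511
0.5,1.0,0.031622776601683793,0.965294220004056327
0.5,1.0,0.1,0.896456979969126642
0.5,1.0,0.31622776601683793,0.723578438477615498
0.5,1.0,1.0,0.427583576155807004
0.5,1.0,3.1622776601683793,0.170577718325972655
0.5,1.0,10.0,0.0561409927438225859
0.5,1.0,31.622776601683793,0.0178323338885420504
0.5,1.0,100.0,0.0056416137829894329
0.5,1.0,316.22776601683793,0.00178411519566599631
0.5,1.0,1000.0,0.000564189301453387654
0.7,0.7,0.001,0.769257078351493126
0.7,0.7,0.0031622776601683793,0.766828642590658958
0.7,0.7,0.01,0.759207543308478316
0.7,0.7,0.031622776601683793,0.735679415009206029
0.7,0.7,0.1,0.666665288701849125
0.7,0.7,0.31622776601683793,0.493315818614551945
0.7,0.7,1.0,0.210393346389023689
0.7,0.7,3.1622776601683793,0.0322536465122222253
0.7,0.7,10.0,0.00272470249310229972
0.7,0.7,31.622776601683793,0.000246066953652559744
0.7,0.7,100.0,0.0000237772055235695809
0.7,0.7,316.22776601683793,2.35182211995183715e-6
0.7,0.7,1000.0,2.34367184862406989e-7
0.7,1.0,0.001,0.998900257182864461
0.7,1.0,0.0031622776601683793,0.996527799589406134
0.7,1.0,0.01,0.989074577350116645
0.7,1.0,0.031622776601683793,0.965988499255719912
0.7,1.0,0.1,0.897561126931386776
0.7,1.0,0.31622776601683793,0.719977392965971281
0.7,1.0,1.0,0.39961197811559939
0.7,1.0,3.1622776601683793,0.130007407966573476
0.7,1.0,10.0,0.0361732655423091581
0.7,1.0,31.622776601683793,0.0108421411918199728
0.7,1.0,100.0,0.00336968741630599427
0.7,1.0,316.22776601683793,0.00105975250113510775
0.7,1.0,1000.0,0.000334541457174099598
0.9,0.9,0.001,0.934705696750722242
0.9,0.9,0.0031622776601683793,0.932389939537945658
0.9,0.9,0.01,0.925106478080281622
0.9,0.9,0.031622776601683793,0.902465212612174511
0.9,0.9,0.1,0.834624747151724919
0.9,0.9,0.31622776601683793,0.653278064388404198
0.9,0.9,1.0,0.308148797776621954
0.9,0.9,3.1622776601683793,0.0384695666055761546
0.9,0.9,10.0,0.0014346523622941286
0.9,0.9,31.622776601683793,0.00010574284157347094
0.9,0.9,100.0,9.78506358890969095e-6
0.9,0.9,316.22776601683793,9.5605105306481869e-7
0.9,0.9,1000.0,9.49170764693391572e-8
0.9,1.0,0.001,0.998960842109997527
0.9,1.0,0.0031622776601683793,0.996717965994548585
0.9,1.0,0.01,0.989661868035365872
0.9,1.0,0.031622776601683793,0.967709063246647776
0.9,1.0,0.1,0.901756942449859404
0.9,1.0,0.31622776601683793,0.723957876150144292
0.9,1.0,1.0,0.376066021424641879
0.9,1.0,3.1622776601683793,0.0764535214390342143
0.9,1.0,10.0,0.0128206060511020999
0.9,1.0,31.622776601683793,0.0035120837317229804
0.9,1.0,100.0,0.00106897241828708904
0.9,1.0,316.22776601683793,0.000334153999057035675
0.9,1.0,1000.0,0.000105288359432095891
1.0,1.0,0.001,0.999000499833374992
1.0,1.0,0.0031622776601683793,0.996842717073532887
1.0,1.0,0.01,0.990049833749168054
1.0,1.0,0.031622776601683793,0.968871994340075427
1.0,1.0,0.1,0.904837418035959573
1.0,1.0,0.31622776601683793,0.728893414110024602
1.0,1.0,1.0,0.367879441171442322
1.0,1.0,3.1622776601683793,0.0423292196232049977
1.0,1.0,10.0,0.0000453999297624848515
1.0,1.0,31.622776601683793,1.8467266624096931e-14
1.0,1.0,100.0,3.72007597602083596e-44
1.0,1.0,316.22776601683793,4.61345399580940244e-138
1.0,1.0,1000.0,5.07595889754945677e-435
0.7,0.7,1.0,0.210393346389023689
0.7,1.0,1.0,0.39961197811559939
0.7,1.0,0.10000000000000001,0.897561126931386771
0.5,0.5,1.0,0.136606007391949283
0.3,1.0,1.0,0.456594408329690671
0.9,1.0,1.0,0.376066021424641879
0.5,1.0,2.0,0.255395676310505744
0.7,1.0,50.0,0.00679366567038309387
0.05,1,2,0.326797850326474288
0.02,1,5,0.16503900415677421
0.1,0.1,3,0.0060745407799221395
0.02,1,0.99,0.499626845049456771
0.001,1,0.9938524759622449,0.501397317537037588
0.05,1,50,0.0190228612770821385
0.15,1,1.5,0.378489825899010426
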