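strain_1,strain_2,strain_3,strain_4,strain_5,strain_6
1.1370958447146668,1.1511521997438938,0.861113929888766,0.755953307142448,1.1895193461264966,1.045545012324122
0.9435301828603911,0.9905340961586903,0.9721211233182628,1.1320113345730192,0.9569530868393801,1.0704837337228819
1.036312841133734,1.2018423713877042,0.9866678663606342,0.9693361405921526,0.974273061723107,1.1035103521969922
1.063286260496104,0.9937285900947579,1.0635950398070075,0.821869156602,0.823683691480522,0.939107362459279
1.0404268323141,1.1304869654223486,0.9715747078583927,0.9828082644240379,1.046009735483127,1.050495512329797
0.9893875483908516,1.2286645392701108,0.7343544579095225,1.1214674699172598,0.9360005124039881,0.8282991320926657
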