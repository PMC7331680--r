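name,x,y,z
Fp1,-0.287496,0.956006,-0.058304
AF7,-0.543245,0.834176,-0.095056
AF3,-0.337915,0.916238,0.215224
F1,-0.283908,0.739023,0.610935
F3,-0.527978,0.724031,0.443868
F5,-0.695942,0.692804,0.188913
F7,-0.762148,0.637402,-0.113354
FT7,-0.927837,0.354159,-0.117006
FC5,-0.872518,0.398716,0.282379
FC3,-0.663036,0.431622,0.611625
FC1,-0.356934,0.439398,0.824335
C1,-0.377936,0.072181,0.923014
C3,-0.711787,0.058368,0.699966
C5,-0.937393,0.038182,0.346174
T7,-0.994956,0.012265,-0.099560
TP7,-0.945229,-0.319117,-0.068607
CP5,-0.880513,-0.322390,0.347509
CP3,-0.662630,-0.307652,0.682841
CP1,-0.351792,-0.291744,0.889454
P1,-0.285469,-0.612982,0.736723
P3,-0.540970,-0.619006,0.569371
P5,-0.718434,-0.623829,0.307719
P7,-0.792761,-0.609270,-0.017892
P9,-0.728730,-0.558788,-0.395864
PO7,-0.569298,-0.821299,0.036984
PO3,-0.376972,-0.843530,0.382557
O1,-0.301770,-0.948518,0.096165
Iz,-0.008926,-0.976772,-0.214095
Oz,-0.008324,-0.987663,0.156373
POz,-0.007204,-0.855812,0.517237
Pz,-0.005774,-0.608852,0.793263
CPz,-0.005216,-0.288845,0.957362
Fpz,-0.007783,0.999935,-0.008373
Fp2,0.272571,0.960334,-0.058854
AF8,0.531775,0.841395,-0.096280
AF4,0.336002,0.915773,0.220141
AFz,-0.006716,0.937691,0.347405
Fz,-0.006125,0.746849,0.664965
F2,0.285292,0.745312,0.602593
F4,0.524490,0.735385,0.429091
F6,0.696160,0.695278,0.178744
F8,0.755693,0.644382,-0.117044
FT8,0.921298,0.370013,-0.119587
FC6,0.868753,0.408981,0.279289
FC4,0.661024,0.439423,0.608239
FC2,0.349509,0.449177,0.822243
FCz,-0.005563,0.444868,0.895579
Cz,-0.005239,0.077927,0.996945
C2,0.379558,0.076899,0.921966
C4,0.715057,0.066631,0.695884
C6,0.938562,0.048806,0.341642
T8,0.994456,0.024195,-0.102329
TP8,0.945415,-0.318178,-0.070376
CP6,0.885481,-0.312038,0.344319
CP4,0.670389,-0.301814,0.677855
CP2,0.362399,-0.290345,0.885645
P2,0.295512,-0.604795,0.739524
P4,0.545412,-0.612752,0.571893
P6,0.714509,-0.627868,0.308640
P8,0.789721,-0.613181,-0.018711
P10,0.721001,-0.566450,-0.399113
PO8,0.561622,-0.826587,0.036541
PO4,0.364176,-0.851090,0.378181
O2,0.289535,-0.952295,0.096455
M1,-0.767260,-0.246224,-0.592188
M2,0.759086,-0.249937,-0.601099
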