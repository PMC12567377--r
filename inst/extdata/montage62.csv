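name,x,y
FP1,-0.247213595499958,0.760845213036123
FPZ,0,0.8
FP2,0.247213595499958,0.760845213036123
AF3,-0.229341389490427,0.647567318991758
AF4,0.229341389490427,0.647567318991758
F7,-0.647213595499958,0.470228201833979
F5,-0.479908036504526,0.48070028548805
F3,-0.315759975449344,0.470632207475511
F1,-0.155580373922125,0.443071167043556
FZ,0,0.4
F2,0.155580373922125,0.443071167043556
F4,0.315759975449344,0.470632207475511
F6,0.479908036504526,0.48070028548805
F8,0.647213595499958,0.470228201833979
FT7,-0.760845213036123,0.247213595499958
FC5,-0.568281913241611,0.257520155843
FC3,-0.377061456239738,0.251334266291085
FC1,-0.187539327911108,0.231630692527523
FCZ,0,0.2
FC2,0.187539327911108,0.231630692527523
FC4,0.377061456239738,0.251334266291085
FC6,0.568281913241611,0.257520155843
FT8,0.760845213036123,0.247213595499958
T7,-0.8,4.89858719658941e-17
C5,-0.6,3.67394039744206e-17
C3,-0.4,2.44929359829471e-17
C1,-0.2,1.22464679914735e-17
CZ,0,0
C2,0.2,1.22464679914735e-17
C4,0.4,2.44929359829471e-17
C6,0.6,3.67394039744206e-17
T8,0.8,4.89858719658941e-17
TP7,-0.760845213036123,-0.247213595499958
CP5,-0.568281913241611,-0.257520155843
CP3,-0.377061456239738,-0.251334266291085
CP1,-0.187539327911108,-0.231630692527523
CPZ,-2.44929359829471e-17,-0.2
CP2,0.187539327911108,-0.231630692527523
CP4,0.377061456239738,-0.251334266291084
CP6,0.568281913241611,-0.257520155843
TP8,0.760845213036123,-0.247213595499958
P7,-0.647213595499958,-0.470228201833978
P5,-0.479908036504526,-0.48070028548805
P3,-0.315759975449344,-0.470632207475511
P1,-0.155580373922125,-0.443071167043556
PZ,-4.89858719658941e-17,-0.4
P2,0.155580373922125,-0.443071167043556
P4,0.315759975449344,-0.470632207475511
P6,0.479908036504526,-0.48070028548805
P8,0.647213595499958,-0.470228201833978
PO7,-0.470228201833979,-0.647213595499958
PO5,-0.308615786809793,-0.653213917596088
PO3,-0.151365593591676,-0.636625982337808
POZ,-7.34788079488412e-17,-0.6
PO4,0.151365593591676,-0.636625982337808
PO6,0.308615786809793,-0.653213917596088
PO8,0.470228201833979,-0.647213595499958
CB1,-0.32681924806675,-0.897928504306535
O1,-0.247213595499958,-0.760845213036123
OZ,-9.79717439317883e-17,-0.8
O2,0.247213595499958,-0.760845213036123
CB2,0.32681924806675,-0.897928504306535
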