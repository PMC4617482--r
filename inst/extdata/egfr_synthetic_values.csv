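name,value
p1,3.8008
p2,4.0832
p3,0.5024
p4,2.897
p5,1.5782
p6,1.0634
p7,2.1416
p8,0.3085
p9,1.6575
p10,1.9349
p11,0.8728
p12,2.0244
p13,4.0518
p14,0.4551
p15,0.8857
p16,4.1221
p17,4.6616
p18,0.2919
p19,0.9227
p20,1.2143
p21,3.6712
p22,0.3126
p23,4.8244
p24,4.2113
p25,0.2608
p26,1.0468
p27,0.7023
p28,3.6915
p29,0.8431
p30,2.9493
p31,2.1485
p32,2.7217
p33,0.6976
p34,1.8149
p35,0.2026
p36,2.9201
p37,0.2048
p38,0.3902
p39,3.7017
x3T,1
x4T,1
x5T,1
x6T,1
x7T,1
x8T,1
x9T,1
x10T,1
x1_0,1
x2_0,1
u1,1
u2,1
u3,1
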