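strain,replicate,max_fc,lambda_max,d,K_qs,inv_B,K_r
blue_01,1,244.72,0.924,0.028,105.9,398.6,0.3999
blue_01,2,198.4,0.9623,0.0277,150.5,355.9,0.382
blue_01,3,263.71,0.838,0.0296,90.2,351.1,0.4238
blue_01,4,181.39,0.9085,0.0291,109.6,371.7,0.4063
blue_02,1,224.5,0.786,0.0339,75.8,349.2,0.2061
blue_02,2,193.69,0.8467,0.0321,111.8,320.1,0.2343
blue_02,3,215.16,0.8603,0.0247,90.8,411.8,0.2598
blue_02,4,201.4,0.9247,0.0225,96.4,368.5,0.2598
blue_03,1,261.63,0.9679,0.0332,86.8,445,0.1994
blue_03,2,220.97,1.0133,0.027,84.8,315.9,0.1527
blue_03,3,263.94,0.9891,0.0257,80.2,443.4,0.1935
blue_03,4,230.46,0.9628,0.0296,73.4,339.1,0.1652
blue_04,1,186.08,0.8266,0.0251,83.3,318.4,0.2209
blue_04,2,152.2,0.8162,0.0325,71.8,327.3,0.2013
blue_04,3,189,0.7875,0.0261,80,358.9,0.2049
blue_04,4,173.09,0.8306,0.0261,82.2,217.4,0.2133
red_01,1,4765.76,1.3371,0.2807,589.3,6073.3,0.2071
red_01,2,4661.26,1.2964,0.2549,406.3,5651.6,0.3107
red_01,3,3802.65,1.3734,0.2483,621.5,6339.6,0.2445
red_01,4,4161.09,1.3453,0.2388,727.7,6087.7,0.236
red_02,1,5233.42,1.2859,0.2639,405.7,7355.7,0.326
red_02,2,4942.45,1.2632,0.2541,718,8254.9,0.3245
red_02,3,5423.3,1.2794,0.251,405.2,6988.6,0.3505
red_02,4,5808.02,1.1589,0.3296,478.4,8904.9,0.4004
red_03,1,3910.01,1.1975,0.2784,542.1,7601.7,0.2121
red_03,2,4067.48,1.2019,0.2075,564.2,6983.8,0.1522
red_03,3,4132.94,1.2741,0.2899,609.4,7871.7,0.1809
red_03,4,5067.02,1.1794,0.2669,765.8,6986.7,0.2061
red_04,1,4708.24,1.268,0.2151,551.4,7442.7,0.1408
red_04,2,4063.83,1.2111,0.2689,582.2,7666.5,0.1184
red_04,3,4140.15,1.179,0.302,553.6,7722.9,0.1485
red_04,4,4157.11,1.1719,0.2451,739.1,6746.4,0.119
green_01,1,2535.75,1.1857,0.0729,1106,5445.7,0.1742
green_01,2,2687.49,1.2163,0.067,640.4,4685.2,0.1398
green_01,3,3109.8,1.1257,0.0831,866.1,5613.3,0.1595
green_01,4,2490.73,1.225,0.0688,525.1,4547.3,0.2037
green_02,1,2796.69,1.1133,0.0589,795.3,5298.1,0.1453
green_02,2,2912.15,1.2699,0.0627,693.9,5069.8,0.1697
green_02,3,3409.17,1.1842,0.0475,1098,4995.1,0.1615
green_02,4,3855.1,1.1124,0.0585,778.1,7297.5,0.194
green_03,1,3337.5,1.1383,0.0579,880.7,5330.3,0.2302
green_03,2,3002.34,1.1727,0.0667,1101,6215.6,0.2003
green_03,3,3419.53,1.1952,0.0618,826.4,5994.4,0.2017
green_03,4,2937.95,1.2846,0.047,751.6,5102.8,0.1847
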