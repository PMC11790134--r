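site,x,y,land_use,Pb,Cr,Mn,Cu,Zn,Co,Ni,As
S1,877.5,1980.4,residential,105.282,287.051,355.5,18.765,85.068,10.949,16.012,19.157
S2,768.5,1091.3,residential,153.447,20.929,311.177,12.268,102.212,14.842,17.381,27.967
S3,279,1070.7,residential,158.645,91.674,339.951,15.132,92.872,12.595,19.203,48.953
S4,529.2,1327.6,residential,144.296,96.258,334.995,9.359,139.278,14.429,18.266,37.399
S5,962.9,1370.1,residential,143.733,61.826,373.673,9.672,87.004,16.041,15.906,24.105
S6,1715.5,1109.1,commercial,53.629,76.726,377.051,20.459,31.08,17.296,30.909,49.872
S7,1757.8,1289.3,commercial,89.07,93.608,365.992,19.074,31.828,20.18,38.707,27.811
S8,1001.9,1819.5,commercial,94.925,73.668,343.047,27.294,21.718,23.469,30.604,56.612
S9,1742.8,1492,commercial,97.871,67.511,334.602,24.27,18.943,15.175,28.563,23.541
S10,1192.4,1030.3,commercial,82.776,57.23,321.811,35.896,86.151,16.026,28.934,22.895
S11,1452.1,1440.2,commercial,89.667,68.141,382.923,23.098,118.754,15.527,20.257,35.366
S12,1322.1,1077.3,commercial,70.311,82.76,322.786,25.18,27.841,18.633,23.073,15.996
S13,176.5,330.9,educational,219.716,113.627,289.62,21.521,43.537,5.572,25.109,35.74
S14,46.3,447.8,educational,149.79,308.477,300.611,23.116,28.149,6.172,27.182,37.596
S15,604.1,834.1,educational,204.056,87.701,331.201,17.123,124.474,7.214,21.486,28.585
S16,660.9,186,educational,173.697,123.721,218.103,18.871,46.013,11.002,23.238,19.232
S17,42.7,511.3,educational,180.313,143.781,340.022,16.139,54.696,8.967,24.094,25.74
S18,449.6,475,educational,177.542,154.671,369.242,23.331,55.766,8.396,23.118,30.734
S19,976.7,466.8,floodplain,117.214,193.742,269.057,32.378,17.979,5.869,31.379,18.386
S20,1273,764.9,floodplain,116.417,250.707,700.059,12.745,20.287,5.153,11.178,12.844
S21,1100.5,435.7,floodplain,133.666,399.165,373.312,114.139,16.394,4.74,21.347,18.251
S22,838,644.3,floodplain,156.048,589.796,260.314,19.452,13.998,5.221,12.802,26.912
S23,1061.9,749,floodplain,128.953,214.438,697.346,26.769,14.762,4.519,36.314,11.989
S24,691.5,404.4,floodplain,142.071,689.801,160.348,13.354,15.977,3.139,19.319,14.401
S25,961.2,657.9,floodplain,137.018,255.213,1065.284,20.52,17.872,6.726,10.23,17.834
S26,1380,510.6,agricultural,166.233,68.434,215.307,79.078,61.98,6.287,16.835,18.67
S27,1656.1,6.7,agricultural,195.285,46.839,234.547,9.358,51.003,7.388,25.847,21.954
S28,1516.8,460.4,agricultural,173.853,926.215,156.635,54.795,57.683,7.666,16.92,11.382
S29,1968.6,269.8,agricultural,185.478,61.3,377.906,14.431,47.541,9.158,19.579,13.904
S30,1416.9,22.3,agricultural,221.422,45.702,154.961,21.318,23.074,3.129,18.582,16.766
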