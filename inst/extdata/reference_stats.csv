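dataset,trait,session,content_mean,content_sd,content_min,content_max,yield_mean,yield_sd,yield_min,yield_max
calib,milk,AM,,,,,12.79,4.27,1.20,37.30
calib,milk,PM,,,,,13.57,4.41,1.20,39.20
calib,milk,daily,,,,,26.36,8.33,2.40,72.80
calib,fat,AM,4.11,0.71,1.01,7.23,515.31,164.29,22.13,1629.96
calib,fat,PM,4.55,0.78,1.12,8.00,605.64,191.21,24.48,1822.35
calib,fat,daily,4.34,0.75,1.07,7.67,1120.94,340.33,46.61,3345.67
calib,sfa,AM,2.76,0.56,0.51,6.95,344.33,111.28,14.49,1272.59
calib,sfa,PM,2.95,0.60,0.54,7.44,392.11,127.91,15.51,1268.89
calib,sfa,daily,2.86,0.58,0.53,7.21,736.41,229.39,30.00,2482.20
calib,mufa,AM,1.15,0.24,0.29,3.84,144.14,53.26,6.08,678.89
calib,mufa,PM,1.36,0.29,0.35,4.56,181.38,64.96,7.22,963.86
calib,mufa,daily,1.26,0.27,0.32,4.22,325.55,114.28,13.31,1562.22
calib,ufa,AM,1.34,0.27,0.37,4.25,168.57,61.34,7.14,765.02
calib,ufa,PM,1.59,0.32,0.44,5.02,210.87,73.76,8.45,1047.49
calib,ufa,daily,1.47,0.29,0.40,4.66,379.44,130.42,15.59,1700.99
calib,scfa,AM,0.38,0.08,0.10,1.02,47.77,16.50,1.63,200.32
calib,scfa,PM,0.40,0.08,0.10,1.08,53.83,18.69,1.73,188.64
calib,scfa,daily,0.39,0.08,0.10,1.06,101.57,33.93,3.36,388.96
calib,mcfa,AM,2.16,0.47,0.06,5.77,268.89,87.51,6.98,975.09
calib,mcfa,PM,2.29,0.50,0.06,6.11,302.83,99.40,9.45,937.77
calib,mcfa,daily,2.22,0.49,0.06,5.96,571.72,179.28,16.43,1891.53
calib,lcfa,AM,1.58,0.35,0.31,5.47,198.89,75.77,6.65,1028.49
calib,lcfa,PM,1.87,0.42,0.37,6.48,249.47,92.22,7.88,1352.77
calib,lcfa,daily,1.73,0.39,0.34,6.01,448.39,162.72,14.53,2195.18
calib,c181,AM,0.75,0.19,0.07,2.97,94.13,38.48,4.51,501.97
calib,c181,PM,0.91,0.23,0.09,3.59,120.85,48.53,5.46,777.79
calib,c181,daily,0.83,0.21,0.08,3.30,214.98,84.65,9.96,1251.72
lux,milk,AM,,,,,12.83,4.46,2.40,30.10
lux,milk,PM,,,,,15.13,5.18,2.80,33.00
lux,milk,daily,,,,,27.96,9.41,5.20,57.00
lux,fat,AM,4.27,0.80,1.05,7.51,537.47,187.33,115.64,1257.44
lux,fat,PM,4.68,0.80,1.59,7.51,695.33,239.95,165.56,1550.10
lux,fat,daily,4.49,0.71,2.33,7.33,1232.80,404.26,321.01,2656.58
lux,sfa,AM,2.91,0.59,0.74,5.03,364.69,126.28,80.44,801.65
lux,sfa,PM,3.14,0.59,1.13,5.90,465.74,159.42,96.15,1075.73
lux,sfa,daily,3.03,0.53,1.50,5.22,830.43,268.59,181.14,1698.26
lux,mufa,AM,1.18,0.29,0.27,3.67,148.79,61.37,29.71,448.47
lux,mufa,PM,1.33,0.30,0.39,3.37,198.17,85.18,52.20,763.26
lux,mufa,daily,1.26,0.27,0.62,3.02,346.97,139.58,111.48,1094.06
lux,ufa,AM,1.40,0.32,0.33,4.08,176.17,70.56,36.82,506.42
lux,ufa,PM,1.56,0.34,0.49,3.75,233.58,97.09,61.22,853.54
lux,ufa,daily,1.49,0.30,0.75,3.37,409.75,159.88,128.22,1229.88
lux,scfa,AM,0.40,0.08,0.10,0.71,51.00,18.47,7.36,112.88
lux,scfa,PM,0.44,0.08,0.17,0.79,65.16,23.18,8.80,145.92
lux,scfa,daily,0.42,0.07,0.24,0.71,116.16,39.48,16.16,240.74
lux,mcfa,AM,2.30,0.47,0.56,3.95,288.14,98.17,53.54,622.87
lux,mcfa,PM,2.47,0.47,0.94,4.11,365.12,121.71,67.72,799.04
lux,mcfa,daily,2.39,0.42,1.15,3.78,653.33,206.66,121.27,1314.99
lux,lcfa,AM,1.66,0.41,0.46,5.29,209.24,87.77,48.90,669.326
lux,lcfa,PM,1.86,0.44,0.55,5.09,278.76,122.40,71.67,1123.44
lux,lcfa,daily,1.77,0.39,0.80,4.49,488.00,200.03,147.86,1582.02
lux,c181,AM,0.81,0.23,0.21,2.85,102.13,46.85,23.20,361.59
lux,c181,PM,0.91,0.24,0.27,2.54,136.21,65.34,35.44,593.22
lux,c181,daily,0.86,0.22,0.43,2.27,238.35,107.11,75.06,852.25
wal,milk,AM,,,,,11.41,4.27,0.20,49.00
wal,milk,PM,,,,,12.70,4.63,0.40,49.00
wal,milk,daily,,,,,24.11,8.64,3.00,75.40
wal,fat,AM,4.00,0.70,0.09,6.61,448.07,166.73,7.21,2730.67
wal,fat,PM,4.47,0.79,0.11,7.40,558.72,204.05,12.86,3418.45
wal,fat,daily,4.25,0.75,0.10,7.22,1006.79,360.00,30.89,4640.37
wal,sfa,AM,2.78,0.56,0.00,5.35,311.57,119.42,0.62,1590.42
wal,sfa,PM,3.00,0.60,0.01,5.79,375.79,142.26,0.42,1854.17
wal,sfa,daily,2.90,0.58,0.00,5.56,687.55,254.50,1.05,2792.34
wal,mufa,AM,1.06,0.24,0.05,3.79,117.76,48.00,1.80,1022.04
wal,mufa,PM,1.27,0.29,0.06,4.56,157.73,62.68,3.98,1458.89
wal,mufa,daily,1.17,0.27,0.06,4.18,275.49,107.92,8.62,1943.96
wal,ufa,AM,1.20,0.26,0.03,3.72,134.10,54.00,2.10,1127.60
wal,ufa,PM,1.44,0.32,0.04,4.47,179.10,70.40,2.80,1588.10
wal,ufa,daily,1.33,0.29,0.03,4.10,313.10,121.30,5.50,2117.50
wal,scfa,AM,0.36,0.08,0.01,0.93,40.79,17.00,0.67,191.11
wal,scfa,PM,0.38,0.08,0.01,0.99,48.52,19.90,0.57,221.20
wal,scfa,daily,0.37,0.08,0.01,0.96,89.31,36.03,1.25,383.54
wal,mcfa,AM,2.18,0.49,0.00,4.49,243.85,94.77,0.63,1095.67
wal,mcfa,PM,2.36,0.53,0.01,4.86,294.22,113.42,0.43,1257.14
wal,mcfa,daily,2.27,0.51,0.00,4.71,538.08,202.61,1.06,2125.97
wal,lcfa,AM,1.46,0.35,0.04,4.41,163.50,68.96,1.50,1503.15
wal,lcfa,PM,1.73,0.41,0.04,5.23,215.80,88.64,0.71,2066.22
wal,lcfa,daily,1.60,0.38,0.04,4.83,379.30,153.91,2.21,2762.95
wal,c181,AM,0.75,0.20,0.01,2.67,83.99,36.72,0.31,820.82
wal,c181,PM,0.89,0.23,0.02,3.17,110.90,47.33,0.29,1185.75
wal,c181,daily,0.83,0.21,0.01,2.97,194.89,82.20,0.60,1585.61
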