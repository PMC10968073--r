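detector,study,scheme,tp,fp,fn,tn,sensitivity,selectivity,precision,accuracy,auc
ws,1,1,1636,8,29,8851,98.26,99.91,99.51,99.65,0.9959
ws,1,2,1044,259,27,8833,97.48,97.15,80.12,97.19,0.8991
ws,1,3,938,70,5,4420,99.47,98.44,93.06,98.62,0.9647
ws,2,1,1623,21,15,8865,99.08,99.76,98.72,99.66,0.9928
ws,2,2,1048,255,9,8851,99.15,97.20,80.43,97.40,0.9015
ws,2,3,938,70,5,4420,99.47,98.44,93.06,98.62,0.9647
ws,3,1,780,11,2,5410,99.74,99.80,98.61,99.79,0.9929
ws,3,2,783,8,10,5402,98.74,99.85,98.99,99.71,0.9940
ws,3,3,786,5,7,5405,99.12,99.91,99.37,99.81,0.9962
ws,3,4,786,5,7,5405,99.12,99.91,99.37,99.81,0.9962
ws,3,5,785,6,7,5405,99.12,99.89,99.24,99.79,0.9956
wf,1,1,1628,16,7,8873,99.57,99.82,99.03,99.78,0.9947
wf,1,2,1030,273,57,8803,94.76,96.99,79.05,96.75,0.8920
wf,1,3,958,50,6,4419,99.38,98.88,95.04,98.97,0.9745
wf,2,1,1615,29,5,8875,99.69,99.67,98.24,99.68,0.9909
wf,2,2,1041,262,109,8751,90.52,97.09,79.89,96.35,0.8933
wf,2,3,915,93,1,4424,99.89,97.94,90.77,98.27,0.9538
wf,3,1,773,18,6,5406,99.23,99.67,97.72,99.61,0.9881
wf,3,2,781,10,6,5406,99.24,99.82,98.74,99.74,0.9931
wf,3,3,780,11,7,5405,99.11,99.80,98.61,99.71,0.9924
wf,3,4,785,6,3,5409,99.62,99.89,99.24,99.85,0.9959
wf,3,5,776,15,1,5411,99.87,99.72,98.10,99.74,0.9904
1d,1,1,1610,34,70,8810,95.83,99.62,97.93,99.01,0.9857
1d,1,2,1048,255,79,8781,92.99,97.18,80.43,96.71,0.8977
1d,1,3,916,92,1,4424,99.89,97.96,90.87,98.29,0.9543
1d,2,1,1554,90,221,8659,87.55,98.97,94.53,97.04,0.9602
1d,2,2,1046,257,53,8807,95.18,97.16,80.28,96.95,0.8984
1d,2,3,946,62,0,4425,100.00,98.62,93.85,98.86,0.9692
1d,3,1,782,9,9,5403,98.86,99.83,98.86,99.71,0.9935
1d,3,2,776,15,14,5398,98.23,99.72,98.10,99.53,0.9892
1d,3,3,783,8,19,5393,97.63,99.85,98.99,99.56,0.9932
1d,3,4,785,6,7,5405,99.12,99.89,99.24,99.79,0.9956
1d,3,5,788,3,3,5409,99.62,99.94,99.62,99.90,0.9978
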