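"ray_id","substance","top_concentration_mM"
"1","nitrite",8.99e-07
"1","ammonia",0.0232
"1","copper",0.00525
"1","aluminum",0.00036
"1","zinc",0.00122
"2","nitrite",1.93e-05
"2","ammonia",0.0301
"2","copper",0.00613
"2","aluminum",0.000148
"2","zinc",0.000911
"3","nitrite",0.000148
"3","ammonia",0.0374
"3","copper",0.00491
"3","aluminum",0.000441
"3","zinc",0.00057
"4","nitrite",0.00079
"4","ammonia",0.0186
"4","copper",0.00583
"4","aluminum",0.000221
"4","zinc",0.00141
"5","nitrite",0.00366
"5","ammonia",0.0267
"5","copper",0.00444
"5","aluminum",0.000539
"5","zinc",0.00106
"6","nitrite",0.017
"6","ammonia",0.0335
"6","copper",0.00555
"6","aluminum",0.000289
"6","zinc",0.000755
"7","nitrite",0.0904
"7","ammonia",0.0421
"7","copper",0.00648
"7","aluminum",0.000672
"7","zinc",0.00164
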