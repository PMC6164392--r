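"subject_id","p","log_xc","AL","AH","unit"
"nitrite",0.26432,-0.77343,0,100,"mg/L"
"ammonia",3.741,-0.24315,0,100,"mg/L"
"zinc",2.88562,-1.09769,0,100,"mg/L"
"aluminum",2.00837,-1.92469,0,100,"mg/L"
"copper",8.05861,-0.431,0,100,"mg/L"
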