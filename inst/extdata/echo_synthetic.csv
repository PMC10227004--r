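"subject_id","group","lvedd_cm","lvesd_cm","ivsd_cm","pwd_cm"
"e01","sham",1.462,0.968,0.301,0.316
"e02","sham",1.429,0.955,0.29,0.316
"e03","sham",1.429,0.902,0.291,0.322
"e04","sham",1.494,0.859,0.266,0.31
"e05","sham",1.427,0.886,0.306,0.313
"e06","rdn",1.536,0.989,0.299,0.296
"e07","rdn",1.483,0.981,0.308,0.294
"e08","rdn",1.392,1.015,0.317,0.305
"e09","rdn",1.461,0.965,0.274,0.284
"e10","rdn",1.458,0.963,0.301,0.304
"e11","hf",1.96,1.543,0.257,0.254
"e12","hf",1.845,1.563,0.251,0.261
"e13","hf",2.084,1.64,0.244,0.277
"e14","hf",1.976,1.624,0.249,0.269
"e15","rdn_hf",1.714,1.371,0.272,0.281
"e16","rdn_hf",1.739,1.344,0.275,0.293
"e17","rdn_hf",1.675,1.28,0.282,0.29
"e18","rdn_hf",1.72,1.372,0.287,0.296
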