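day,mouse_id,population,count
7,m01,C,75268.3113347392
7,m01,T,2551208.88630894
7,m01,M,3356.14749166395
7,m02,C,65032.3663171987
7,m02,T,3090903.91303491
7,m02,M,3058.30809823105
13,m03,C,101668.354432339
13,m03,T,3187582.96317116
13,m03,M,6560.66149916181
13,m04,C,74436.834614043
13,m04,T,4205649.24427461
13,m04,M,6918.5807013866
20,m05,C,70446.20286402
20,m05,T,3388204.54773607
20,m05,M,5471.52714184991
20,m06,C,105198.325631817
20,m06,T,3384540.04220489
20,m06,M,3319.68778007696
24,m07,C,61931.3731752612
24,m07,T,4825369.31623651
24,m07,M,5811.97844997836
24,m08,C,70567.3862357381
24,m08,T,3590897.7139865
24,m08,M,7855.43202345623
27,m09,C,153003.603957928
27,m09,T,3484659.21503162
27,m09,M,6201.1704223448
27,m10,C,74139.7996914128
27,m10,T,4156776.93949856
27,m10,M,5748.51898149991
34,m11,C,123819.453033444
34,m11,T,4513099.96413435
34,m11,M,8756.72633370698
34,m12,C,100286.693258955
34,m12,T,4337938.16217502
34,m12,M,5077.34137270999
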