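sample_id,condition,feature,deg0,deg45,deg90,deg135,mu
A0065,OOS,ASM,0.110,0.097,0.111,0.097,0.104
A0065,OOS,CON,0.201,0.266,0.192,0.266,0.231
A0065,OOS,COR,0.963,0.951,0.965,0.951,0.957
A0065,OOS,ENT,3.524,3.683,3.499,3.683,3.597
A0418,OOS,ASM,0.123,0.109,0.125,0.109,0.117
A0418,OOS,CON,0.172,0.227,0.161,0.227,0.197
A0418,OOS,COR,0.967,0.956,0.969,0.956,0.962
A0418,OOS,ENT,3.418,3.575,3.386,3.575,3.489
A0053,OOS,ASM,0.157,0.142,0.158,0.142,0.149
A0053,OOS,CON,0.145,0.196,0.142,0.196,0.170
A0053,OOS,COR,0.962,0.949,0.963,0.949,0.956
A0053,OOS,ENT,3.156,3.314,3.147,3.314,3.233
A0802,IS,ASM,0.180,0.164,0.181,0.164,0.172
A0802,IS,CON,0.139,0.186,0.136,0.186,0.162
A0802,IS,COR,0.951,0.934,0.952,0.934,0.943
A0802,IS,ENT,2.943,3.093,2.933,3.093,3.016
A0804,IS,ASM,0.151,0.137,0.153,0.137,0.144
A0804,IS,CON,0.148,0.198,0.142,0.198,0.171
A0804,IS,COR,0.963,0.951,0.965,0.951,0.957
A0804,IS,ENT,3.192,3.344,3.172,3.344,3.263
A0801,IS,ASM,0.172,0.156,0.173,0.156,0.164
A0801,IS,CON,0.151,0.200,0.146,0.200,0.174
A0801,IS,COR,0.952,0.937,0.954,0.937,0.945
A0801,IS,ENT,3.037,3.184,3.020,3.184,3.106
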