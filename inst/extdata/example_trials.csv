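cricket,condition,sx,attempt,left_tube,seconds
VF01,clean,M,1,1,143
VF01,clean,M,2,1,121
VF01,clean,M,3,0,
VF01,clean,M,4,1,98
VF02,clean,F,1,1,230
VF02,clean,F,2,1,212
VF02,clean,F,3,1,205
VF02,clean,F,4,1,170
IN01,addv,M,1,0,
IN01,addv,M,2,0,
IN01,addv,M,3,1,410
IN01,addv,M,4,0,
IN02,addv,F,1,1,356
IN02,addv,F,2,0,
IN02,addv,F,3,1,301
IN02,addv,F,4,1,288
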