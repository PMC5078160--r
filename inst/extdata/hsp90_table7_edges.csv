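set_id,from,to,exp_ddg,value1,se1,label1,value2,se2,label2,selected
1,ref,80,NA,1.8,0.5,conf1,-3.6,0.5,conf2,2
1,81,82,10.0,-13.2,0.5,conf1,-16.4,0.5,conf2,1
1,82,ref,NA,13.3,0.3,conf1,16.4,0.3,conf2,2
1,83,ref,NA,3.6,0.5,conf1,-3.5,0.5,conf2,1
1,84,ref,NA,8.3,0.5,conf1,8.3,0.6,conf2,1
3,10,ref2,NA,-4.9,0.4,conf1,-0.6,0.4,conf2,2
3,11,ref2,NA,2.3,0.2,conf1,NA,NA,NA,1
3,15,ref3,NA,4.8,0.5,conf1,-4.1,0.6,conf2,1
3,19,ref1,NA,2.9,0.6,conf1,NA,NA,NA,1
3,21,ref3,NA,7.3,0.4,conf1,-2.1,0.4,conf2,1
3,23,ref2,NA,-6.7,0.5,conf1,-13.1,0.6,conf2,1
3,26,ref2,NA,3.7,0.4,conf1,-12.0,0.4,conf2,1
3,28,ref2,NA,1.3,0.4,conf1,-1.9,0.4,conf2,1
3,34,ref2,NA,-0.2,0.7,conf1,-3.7,0.7,conf2,1
3,61S,ref2,NA,-4.8,0.8,S,NA,NA,NA,1
3,61R,ref2,NA,-19.8,0.4,R,NA,NA,NA,1
3,ref2,ref1,NA,-11.5,0.6,conf1,NA,NA,NA,1
3,ref3,ref2,NA,4.5,0.4,conf1,NA,NA,NA,1
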