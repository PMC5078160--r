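block,structure,from,to,exp_ddg,value,se
without_wat,2WI7,101,100,13.9,-12.2,0.5
without_wat,2WI7,101,105,-0.1,-7.5,0.2
without_wat,2WI7,101,106,2.0,-7.3,0.3
without_wat,3FT5,101,100,13.9,2.7,0.5
without_wat,3FT5,101,105,-0.1,2.7,0.2
without_wat,3FT5,101,106,2.0,3.8,0.3
without_wat,2WI7_3FT5,101,100,13.9,-12.8,0.5
without_wat,2WI7_3FT5,101,105,-0.1,-8.4,0.2
without_wat,2WI7_3FT5,101,106,2.0,-8.7,0.3
with_wat,2WI7,101,100,13.9,11.2,0.9
with_wat,2WI7,101,105,-0.1,-6.2,0.4
with_wat,2WI7,101,106,2.0,-3.7,0.5
with_wat,3FT5,101,100,13.9,18.0,0.9
with_wat,3FT5,101,105,-0.1,3.5,0.4
with_wat,3FT5,101,106,2.0,5.5,0.5
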