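ligand,set_id,block,exp_dg,gscore,emodel,ifdscore,mmgbsa,non_binder
80,1,set1,-32.6,-42.6,-326.8,-2079.7,-367.9,FALSE
81,1,set1,-38.2,-46.9,-398.1,-2086.9,-379.7,FALSE
82,1,set1,-28.2,-47.0,-378.7,-2083.8,-395.5,FALSE
83,1,set1,-27.5,-45.4,-375.6,-2085.9,-413.1,FALSE
84,1,set1,-29.9,-45.4,-368.3,-2081.5,-405.6,FALSE
100,2,set2_3VHA,-24.6,-41.3,-333.9,-2054.0,-342.8,FALSE
101,2,set2_3VHA,-38.3,-38.7,-289.5,-2047.0,-311.1,FALSE
105,2,set2_3VHA,-39.5,-37.4,-300.7,-2046.5,-319.5,FALSE
106,2,set2_3VHA,-40.3,-37.8,-308.4,-2046.6,-298.7,FALSE
100,2,set2_2WI7,-24.6,-39.7,-282.2,-1973.7,-357.2,FALSE
101,2,set2_2WI7,-38.3,-38.4,-282.9,-1973.4,-310.9,FALSE
105,2,set2_2WI7,-39.5,-40.7,-307.1,-1978.7,-348.0,FALSE
106,2,set2_2WI7,-40.3,-39.5,-309.7,-1974.8,-338.8,FALSE
10,3,set3,-30.3,-51.5,-444.6,-1980.7,-292.2,FALSE
11,3,set3,-38.1,-46.9,-401.6,-1977.9,-307.1,FALSE
15,3,set3,-29.5,-54.1,-512.3,-1988.8,-347.7,FALSE
19,3,set3,-29.6,-47.8,-444.2,-1980.4,-306.3,FALSE
21,3,set3,-38.3,-54.2,-493.0,-1989.1,-395.8,FALSE
23,3,set3,-31.5,-50.3,-468.3,-1985.9,-333.7,FALSE
26,3,set3,-43.9,-53.7,-458.7,-1987.1,-383.3,FALSE
28,3,set3,-37.4,-54.4,-457.6,-1986.9,-316.1,FALSE
34,3,set3,-29.7,-51.4,-447.2,-1991.3,-305.0,FALSE
61,3,set3,-24.6,-50.2,-415.5,-1981.7,-271.4,TRUE
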