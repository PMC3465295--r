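population,level,nesters,nests_per_female,eggs_per_nest,hatching_success,emergence,beach_survival,water_survival
EP,low,248,4.3,61.3,0.39,0.51,0.78,0.64
EP,mean,248,6.1,64.1,0.47,0.76,0.83,0.69
EP,high,248,7.9,66.9,0.55,1,0.87,0.74
WP,low,1113,4.3,73.2,0.39,0.51,0.78,0.64
WP,mean,1113,6.1,77.9,0.47,0.76,0.83,0.69
WP,high,1113,7.9,82.6,0.55,1,0.87,0.74
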