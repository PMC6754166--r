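"strategy","statistic","value","weight"
"current_practice","LE",64.5,1
"current_practice","median",41.5,0.5
"optimized","LE",76.7,1
"optimized","median",47.5,0.5
"optimized_ip","LE",71.7,1
"optimized_ip","median",44.5,0.5
"optimized_bev","LE",65,1
"optimized_bev","median",41.5,0.5
"optimized_hipec","LE",69,1
"optimized_hipec","median",43.5,0.5
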