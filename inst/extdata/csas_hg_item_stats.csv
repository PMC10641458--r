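variable,n,mean,sd,difficulty,discrimination,scale_max
computer,842,2.9,2.0,0.48,0.21,6
game_console,843,1.8,1.8,0.30,0.31,6
portable_console,835,1.0,1.6,0.17,0.24,6
mobile_phone,860,3.5,2.1,0.58,0.27,6
gaming_time,764,52,52,0.45,0.52,NA
item11,839,0.4,0.8,0.13,0.61,3
item15,840,0.2,0.5,0.07,0.63,3
item6,838,0.2,0.5,0.07,0.62,3
item14,839,0.5,0.8,0.17,0.65,3
item16,837,0.1,0.4,0.03,0.60,3
item18,838,0.1,0.3,0.03,0.44,3
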