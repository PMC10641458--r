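variable,computer,game_console,portable_console,mobile_phone,gaming_time,item11,item15,item6,item14,item16,item18
computer,1,0.20,0.10,0.12,0.24,0.20,0.14,0.15,0.18,0.11,0.12
game_console,0.20,1,0.26,0.25,0.29,0.20,0.15,0.17,0.28,0.16,0.13
portable_console,0.10,0.26,1,0.08,0.17,0.14,0.15,0.16,0.22,0.11,0.09
mobile_phone,0.12,0.25,0.08,1,0.39,0.21,0.16,0.19,0.27,0.15,0.11
gaming_time,0.24,0.29,0.17,0.39,1,0.34,0.38,0.33,0.45,0.28,0.13
item11,0.20,0.20,0.14,0.21,0.34,1,0.62,0.42,0.57,0.43,0.40
item15,0.14,0.15,0.15,0.16,0.38,0.62,1,0.49,0.54,0.52,0.43
item6,0.15,0.17,0.16,0.19,0.33,0.42,0.49,1,0.53,0.65,0.36
item14,0.18,0.28,0.22,0.27,0.45,0.57,0.54,0.53,1,0.45,0.28
item16,0.11,0.16,0.11,0.15,0.28,0.43,0.52,0.65,0.45,1,0.48
item18,0.12,0.13,0.09,0.11,0.13,0.40,0.43,0.36,0.28,0.48,1
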