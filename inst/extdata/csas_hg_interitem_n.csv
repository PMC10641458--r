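variable,computer,game_console,portable_console,mobile_phone,gaming_time,item11,item15,item6,item14,item16,item18
computer,842,828,819,836,743,812,813,811,812,810,811
game_console,828,843,822,834,746,813,814,812,813,811,812
portable_console,819,822,835,830,741,804,805,803,804,802,804
mobile_phone,836,834,830,860,758,828,829,827,828,826,827
gaming_time,743,746,741,758,764,740,740,740,739,737,738
item11,812,813,804,828,740,839,839,838,838,836,837
item15,813,814,805,829,740,839,840,838,839,837,838
item6,811,812,803,827,740,838,838,838,837,835,836
item14,812,813,804,828,739,838,839,837,839,837,837
item16,810,811,802,826,737,836,837,835,837,837,835
item18,811,812,804,827,738,837,838,836,837,835,838
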