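category,label,computer,game_console,portable_console,mobile_phone
0,never,182,337,541,139
1,once_or_twice,79,100,76,51
2,three_to_twelve_times,105,141,81,105
3,multiple_times_per_month,115,93,56,82
4,once_a_week,84,63,27,60
5,multiple_times_a_week,225,92,44,287
6,daily,52,17,10,136
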