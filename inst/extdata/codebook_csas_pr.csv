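item_id,scale_min,scale_max,role,criterion,item_pair_index
item1,0,3,igd_item,preoccupation,1
item9,0,3,igd_item,preoccupation,2
item2,0,3,igd_item,tolerance,1
item10,0,3,igd_item,tolerance,2
item3,0,3,igd_item,withdrawal,1
item12,0,3,igd_item,withdrawal,2
item4,0,3,igd_item,loss_of_control,1
item13,0,3,igd_item,loss_of_control,2
item5,0,3,igd_item,escape_mood,1
item17,0,3,igd_item,escape_mood,2
item6,0,3,igd_item,continue_despite_problems,1
item14,0,3,igd_item,continue_despite_problems,2
item7,0,3,igd_item,deception,1
item8,0,3,igd_item,deception,2
item11,0,3,igd_item,give_up_activities,1
item15,0,3,igd_item,give_up_activities,2
item16,0,3,igd_item,risk_lose,1
item18,0,3,igd_item,risk_lose,2
freq_computer,0,6,frequency_item,computer,1
freq_game_console,0,6,frequency_item,game_console,1
freq_portable_console,0,6,frequency_item,portable_console,1
freq_mobile_phone,0,6,frequency_item,mobile_phone,1
weekday_minutes,NA,NA,time_item,weekday,1
weekend_minutes,NA,NA,time_item,weekend,1
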