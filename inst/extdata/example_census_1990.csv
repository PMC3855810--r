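tree_id,species,x,y,dbh_mm,status,palm,main_stem,stem_issue
t000010,sp005,10.2094483282417,33.9374297857285,249.3,alive,0,1,0
t000017,sp005,1.85485100373626,29.1334865801036,21.7,alive,0,1,0
t000053,sp005,5.73055969551206,33.9550869725645,NA,dead,0,1,0
t000054,sp006,24.4563423469663,5.95684575848281,48.9,alive,0,1,0
t000078,sp002,5.98008202388883,15.7564677949995,18.5,alive,0,1,0
t000145,sp003,18.9660542737693,29.3382176943123,74,alive,0,1,0
t000149,sp006,3.21155650541186,15.4206354450434,45.1,alive,0,1,0
t000250,sp006,23.6100672092289,28.6088609695435,174.2,alive,0,1,0
t000348,sp005,19.9438656214625,17.3377039842308,192.9,alive,0,1,0
t000398,sp002,19.7236314695328,38.091877810657,120.3,alive,0,1,0
t000416,sp002,28.2341498415917,30.124272685498,25.8,alive,0,1,0
t000461,sp002,4.11441014148295,39.1562385577708,40.7,alive,0,1,0
t000527,sp002,6.72972095198929,0.873541487380862,20.7,alive,0,1,0
t000542,sp003,38.6415600124747,16.5230993926525,36.9,alive,0,1,0
t000571,sp005,16.5849483665079,9.27817300893366,28.7,alive,0,1,0
r00001,sp001,12.2,8.9,11,alive,0,1,0
r00002,sp003,30.5,22.1,14,alive,0,1,0
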