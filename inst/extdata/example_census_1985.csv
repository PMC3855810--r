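tree_id,species,x,y,dbh_mm,status,palm,main_stem,stem_issue
t000010,sp005,10.2094483282417,33.9374297857285,243.227461510684,alive,0,1,0
t000017,sp005,1.85485100373626,29.1334865801036,15.4042396407138,alive,0,1,0
t000053,sp005,5.73055969551206,33.9550869725645,32.1870891729448,alive,0,1,0
t000054,sp006,24.4563423469663,5.95684575848281,43.4907569358577,alive,0,1,0
t000078,sp002,5.98008202388883,15.7564677949995,12.1982561240309,alive,0,1,0
t000145,sp003,18.9660542737693,29.3382176943123,68.496515438691,alive,0,1,0
t000149,sp006,3.21155650541186,15.4206354450434,38.1005305826104,alive,0,1,0
t000250,sp006,23.6100672092289,28.6088609695435,173.925398821929,alive,0,1,0
t000348,sp005,19.9438656214625,17.3377039842308,178.951711487047,alive,0,1,0
t000398,sp002,19.7236314695328,38.091877810657,113.14362935611,alive,0,1,0
t000416,sp002,28.2341498415917,30.124272685498,20.2098197965582,alive,0,1,0
t000461,sp002,4.11441014148295,39.1562385577708,26.3727912590522,alive,0,1,0
t000527,sp002,6.72972095198929,0.873541487380862,14.9310287391615,alive,0,1,0
t000542,sp003,38.6415600124747,16.5230993926525,28.4242880423149,alive,0,1,0
t000571,sp005,16.5849483665079,9.27817300893366,14.9546584573962,alive,0,1,0
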