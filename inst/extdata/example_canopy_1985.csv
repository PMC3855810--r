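year,cell_x,cell_y,L1,L2,L3,L4,L5,L6
1985,0,0,1,1,1,1,0,0
1985,1,0,1,1,1,1,0,0
1985,2,0,1,1,1,1,0,0
1985,3,0,1,1,1,1,0,0
1985,4,0,1,1,1,1,0,0
1985,5,0,1,1,1,1,0,0
1985,6,0,1,1,1,1,0,0
1985,7,0,1,1,1,1,0,0
1985,0,1,1,1,1,1,0,0
1985,1,1,1,1,1,1,0,0
1985,2,1,1,1,1,1,0,0
1985,3,1,1,1,1,1,0,0
1985,4,1,1,1,1,1,0,0
1985,5,1,1,1,1,1,0,0
1985,6,1,1,1,1,1,0,0
1985,7,1,1,1,1,1,0,0
1985,0,2,1,1,1,1,0,0
1985,1,2,1,1,1,1,0,0
1985,2,2,1,1,1,1,0,0
1985,3,2,1,1,1,1,0,0
1985,4,2,1,1,1,1,0,0
1985,5,2,1,1,1,1,0,0
1985,6,2,1,1,1,1,0,0
1985,7,2,1,1,1,1,0,0
1985,0,3,1,1,1,1,0,0
1985,1,3,1,1,1,1,0,0
1985,2,3,1,1,1,1,0,0
1985,3,3,1,1,1,1,0,0
1985,4,3,1,1,1,1,0,0
1985,5,3,1,1,1,1,0,0
1985,6,3,1,1,1,1,0,0
1985,7,3,1,1,1,1,0,0
1985,0,4,1,1,1,1,0,0
1985,1,4,1,1,1,1,0,0
1985,2,4,1,1,1,0,0,0
1985,3,4,1,1,1,1,0,0
1985,4,4,1,1,1,1,0,0
1985,5,4,1,1,1,1,0,0
1985,6,4,1,1,1,1,0,0
1985,7,4,1,1,1,1,0,0
1985,0,5,1,1,1,1,0,0
1985,1,5,1,1,1,1,1,0
1985,2,5,1,1,1,1,1,0
1985,3,5,0,1,1,1,1,0
1985,4,5,1,1,1,1,0,0
1985,5,5,1,1,1,1,0,0
1985,6,5,1,1,1,1,0,0
1985,7,5,1,1,1,1,0,0
1985,0,6,1,1,1,1,0,0
1985,1,6,1,1,1,1,1,0
1985,2,6,1,1,1,1,1,0
1985,3,6,1,1,1,1,1,0
1985,4,6,1,1,1,1,0,0
1985,5,6,1,1,1,1,0,0
1985,6,6,1,1,1,1,0,0
1985,7,6,0,1,1,1,0,0
1985,0,7,1,1,1,1,0,0
1985,1,7,1,1,1,1,0,0
1985,2,7,1,1,1,1,1,0
1985,3,7,1,1,1,1,0,0
1985,4,7,1,1,1,1,0,0
1985,5,7,1,1,1,1,0,0
1985,6,7,1,1,1,1,0,0
1985,7,7,1,1,1,1,0,0
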