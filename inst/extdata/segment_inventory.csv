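script,segment_id,x1,y1,x2,y2
arabic_sevenseg,a,0,2,1,2
arabic_sevenseg,b,1,1,1,2
arabic_sevenseg,c,1,0,1,1
arabic_sevenseg,d,0,0,1,0
arabic_sevenseg,e,0,0,0,1
arabic_sevenseg,f,0,1,0,2
arabic_sevenseg,g,0,1,1,1
mandarin,h_top,0.1,0.9,0.9,0.9
mandarin,h_mid,0.2,0.5,0.8,0.5
mandarin,h_bot,0,0.05,1,0.05
mandarin,d_left5,0.45,0.9,0.28,0.05
mandarin,v_right,0.68,0.5,0.68,0.05
mandarin,v_left,0.1,0.9,0.1,0.05
mandarin,d_in4a,0.38,0.9,0.3,0.4
mandarin,v_in4b,0.58,0.9,0.62,0.4
mandarin,t_dot,0.5,1,0.54,0.88
mandarin,d_bl,0.32,0.45,0.12,0.05
mandarin,d_br,0.68,0.45,0.88,0.05
mandarin,v_cen7,0.5,0.95,0.46,0.12
mandarin,h_hook7,0.46,0.12,0.82,0.16
mandarin,d_left9,0.42,0.95,0.1,0.05
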