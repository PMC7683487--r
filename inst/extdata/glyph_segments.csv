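script,value,variant,segment_id
arabic_sevenseg,1,std,b
arabic_sevenseg,1,std,c
arabic_sevenseg,2,std,a
arabic_sevenseg,2,std,b
arabic_sevenseg,2,std,g
arabic_sevenseg,2,std,e
arabic_sevenseg,2,std,d
arabic_sevenseg,3,std,a
arabic_sevenseg,3,std,b
arabic_sevenseg,3,std,g
arabic_sevenseg,3,std,c
arabic_sevenseg,3,std,d
arabic_sevenseg,4,std,f
arabic_sevenseg,4,std,g
arabic_sevenseg,4,std,b
arabic_sevenseg,4,std,c
arabic_sevenseg,5,std,a
arabic_sevenseg,5,std,f
arabic_sevenseg,5,std,g
arabic_sevenseg,5,std,c
arabic_sevenseg,5,std,d
arabic_sevenseg,6,with_top,a
arabic_sevenseg,6,with_top,c
arabic_sevenseg,6,with_top,d
arabic_sevenseg,6,with_top,e
arabic_sevenseg,6,with_top,f
arabic_sevenseg,6,with_top,g
arabic_sevenseg,7,with_serif,a
arabic_sevenseg,7,with_serif,b
arabic_sevenseg,7,with_serif,c
arabic_sevenseg,7,with_serif,f
arabic_sevenseg,8,std,a
arabic_sevenseg,8,std,b
arabic_sevenseg,8,std,c
arabic_sevenseg,8,std,d
arabic_sevenseg,8,std,e
arabic_sevenseg,8,std,f
arabic_sevenseg,8,std,g
arabic_sevenseg,9,open_tail,a
arabic_sevenseg,9,open_tail,b
arabic_sevenseg,9,open_tail,c
arabic_sevenseg,9,open_tail,f
arabic_sevenseg,9,open_tail,g
mandarin,1,std,h_mid
mandarin,2,std,h_top
mandarin,2,std,h_bot
mandarin,3,std,h_top
mandarin,3,std,h_mid
mandarin,3,std,h_bot
mandarin,4,std,h_top
mandarin,4,std,h_bot
mandarin,4,std,v_left
mandarin,4,std,v_right
mandarin,4,std,d_in4a
mandarin,4,std,v_in4b
mandarin,5,std,h_top
mandarin,5,std,h_mid
mandarin,5,std,h_bot
mandarin,5,std,d_left5
mandarin,5,std,v_right
mandarin,6,std,t_dot
mandarin,6,std,h_top
mandarin,6,std,d_bl
mandarin,6,std,d_br
mandarin,7,std,h_mid
mandarin,7,std,v_cen7
mandarin,7,std,h_hook7
mandarin,8,std,d_bl
mandarin,8,std,d_br
mandarin,9,std,d_left9
mandarin,9,std,h_mid
mandarin,9,std,v_right
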