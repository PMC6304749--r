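scenario,maturation,stp_class,if_hz,msf_before_hz,msf_after_hz,printed_pct,printed_direction,consistent,note
B-2,immature,STD1,5,25.8,18.0,30.2,reduction,TRUE,
B-2,immature,STF2,5,25.8,6.0,76.7,reduction,TRUE,
B-2,immature,STF1,10,53.0,17.0,67.9,reduction,TRUE,
B-2,immature,STF1,15,47.0,18.0,61.7,reduction,TRUE,
B-2,immature,STF2,15,47.0,24.0,48.9,reduction,TRUE,
B-2,immature,STF1,20,54.0,35.8,22.5,reduction,FALSE,recomputes to 33.7
B-2,immature,STF1,30,85.0,49.0,33.7,reduction,FALSE,printed twice (33.7 and 42.3); recomputes to 42.4
B-2,immature,STF2,30,85.0,43.8,48.5,reduction,TRUE,
B-3,immature,STD1,80,133.8,15.2,88.6,reduction,TRUE,
B-4,immature,STD1,40,110.0,60.5,45.0,reduction,TRUE,
B-1,immature,STF2,20,65.0,78.2,20.3,increase,TRUE,
B-1,immature,STF2,45,90.5,65.5,27.6,reduction,TRUE,
B-1,immature,STD1,80,139.0,72.8,47.6,reduction,TRUE,
B-1,immature,STD1,20,65.0,36.0,44.6,reduction,TRUE,
B-1,immature,STF1,20,65.0,38.0,41.5,reduction,TRUE,
B-1,immature,STD2,25,62.5,39.8,36.3,reduction,TRUE,
B-2,immature,STF2,40,112.0,66.8,40.3,reduction,FALSE,recomputes to 40.4 (truncated print)
B-2,immature,STF1,50,86.0,82.0,4.6,reduction,FALSE,recomputes to 4.7 (truncated print)
B-2,immature,STF2,50,86.0,76.0,11.6,reduction,TRUE,
B-2,immature,STD2,100,152.7,89.5,41.4,reduction,TRUE,
B-3,immature,STD1,55,108.2,64.9,40.0,reduction,TRUE,
B-3,immature,STD2,55,108.2,66.5,38.5,reduction,TRUE,
B-3,immature,STD2,80,133.8,72.8,45.6,reduction,TRUE,
B-4,immature,STF2,20,107.7,127.0,17.9,increase,TRUE,
B-4,immature,STF1,45,110.5,76.0,31.2,reduction,TRUE,
B-4,immature,STF2,45,110.5,67.2,39.2,reduction,TRUE,
B-4,immature,STF1,55,109.1,81.0,25.7,reduction,FALSE,recomputes to 25.8 (truncated print)
B-4,immature,STF2,55,109.1,94.5,13.4,reduction,TRUE,
B-4,immature,STD2,80,136.5,133.5,2.2,reduction,TRUE,
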