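# t_start: 0
# t_stop: 250
trial_id,unit_id,time_ms
1,u1,2.5
1,u1,52.5
1,u1,102.5
1,u1,152.5
1,u1,202.5
1,u2,7.5
1,u2,57.5
1,u2,107.5
1,u2,157.5
1,u2,207.5
1,u3,17.5
1,u3,67.5
1,u3,117.5
1,u3,167.5
1,u3,217.5
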