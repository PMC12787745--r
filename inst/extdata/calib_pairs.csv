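coordinate_id,antenna_id,rssi_dbm,distance_m
1,A,-42.83,2.33
1,B,-58.67,2.53
1,C,-60.5,2.2
2,A,-54.33,2.16
2,B,-57.17,2.25
2,C,-60.33,2.54
3,A,-69,3.58
3,B,,
3,C,-67,2.73
4,A,,
4,B,,
4,C,-62.17,2.5
5,A,,
5,B,,
5,C,-66.83,2.75
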