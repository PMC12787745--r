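antenna_id,rssi_dbm
A,-58.00
A,-58.00
A,-62.00
A,-54.00
A,-62.00
A,-65.00
A,-64.00
A,-62.00
A,-63.00
A,-64.00
A,-65.00
A,-64.00
B,-54.00
B,-53.00
B,-56.00
B,-56.00
B,-53.00
B,-51.00
B,-52.00
B,-52.00
B,-51.00
B,-51.00
B,-48.00
B,-54.00
C,-51.00
C,-49.00
C,-47.00
C,-47.00
C,-50.00
C,-50.00
C,-49.00
C,-50.00
C,-48.00
C,-49.00
C,-47.00
C,-50.00
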