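day1,day2,day3
59.9,67.7,72.2
62.9,66.5,67.9
58.9,50.1,47.9
46.8,50.0,53.9
62.5,67.8,62.6
44.8,42.7,48.4
57.3,49.6,48.0
49.0,45.2,57.5
43.5,41.5,47.4
39.2,50.9,56.3
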