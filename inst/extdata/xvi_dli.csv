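phantom,kvp,collimator,dli_center,dli_periphery,dlp_published
head,100,S10,32.9,41.7,38.7
head,100,S20,68.3,83.3,78.2
body,120,S10,51.8,69.0,63.2
body,120,S20,100.8,127.1,118.2
body,120,M10,48.1,57.6,54.4
body,120,M15,62.5,73.4,69.7
body,120,M20,93.4,107.0,102.3
body,120,L10,38.6,42.7,41.3
body,120,L20,72.5,78.3,76.3
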