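phantom,kvp,rotation,collimator,position,dose_cgy_per_100mas
body,120,full,S10,center,0.30
body,120,full,S10,A,0.38
body,120,full,S10,L,0.43
body,120,full,S10,P,0.35
body,120,full,S10,R,0.45
body,120,full,S20,center,0.36
body,120,full,S20,A,0.44
body,120,full,S20,L,0.49
body,120,full,S20,P,0.41
body,120,full,S20,R,0.50
body,120,full,M10,center,0.28
body,120,full,M10,A,0.34
body,120,full,M10,L,0.33
body,120,full,M10,P,0.32
body,120,full,M10,R,0.36
body,120,full,M15,center,0.31
body,120,full,M15,A,0.37
body,120,full,M15,L,0.35
body,120,full,M15,P,0.35
body,120,full,M15,R,0.38
body,120,full,M20,center,0.34
body,120,full,M20,A,0.39
body,120,full,M20,L,0.37
body,120,full,M20,P,0.38
body,120,full,M20,R,0.41
body,120,full,L10,center,0.23
body,120,full,L10,A,0.25
body,120,full,L10,L,0.25
body,120,full,L10,P,0.23
body,120,full,L10,R,0.28
body,120,full,L20,center,0.26
body,120,full,L20,A,0.28
body,120,full,L20,L,0.28
body,120,full,L20,P,0.26
body,120,full,L20,R,0.32
head,100,full,S10,center,0.23
head,100,full,S10,A,0.29
head,100,full,S10,L,0.28
head,100,full,S10,P,0.28
head,100,full,S10,R,0.30
head,100,full,S20,center,0.25
head,100,full,S20,A,0.31
head,100,full,S20,L,0.31
head,100,full,S20,P,0.30
head,100,full,S20,R,0.31
head,100,half,S10,center,0.23
head,100,half,S10,A,0.15
head,100,half,S10,L,0.31
head,100,half,S10,P,0.40
head,100,half,S10,R,0.28
head,100,half,S20,center,0.26
head,100,half,S20,A,0.16
head,100,half,S20,L,0.33
head,100,half,S20,P,0.44
head,100,half,S20,R,0.30
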