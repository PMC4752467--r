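batch_id,UR,AD,CGA,CFA,CCA,LGR,LG,P7C
S1,109.0,78.9,137.8,88.0,84.6,76.9,71.6,92.4
S2,89.9,192.7,104.8,57.0,87.4,77.5,72.7,97.4
S3,89.9,150.2,86.9,89.7,90.5,85.7,57.9,93.0
S4,80.6,122.2,94.4,94.3,93.8,91.0,67.8,92.0
S5,83.9,142.7,81.8,88.4,90.4,85.4,58.3,90.1
S6,71.4,130.9,86.6,94.9,88.2,84.1,60.3,88.1
S7,71.8,53.3,105.9,115.8,111.7,88.7,82.5,89.9
S8,116.3,90.9,116.5,136.3,131.4,92.0,82.7,109.4
S9,98.2,40.9,104.2,101.8,104.0,73.5,60.0,83.2
S10,128.7,219.9,123.1,100.8,88.9,83.8,55.1,114.3
S11,105.2,51.1,111.3,110.9,118.9,89.2,85.6,96.0
S12,100.6,57.6,107.1,107.2,107.9,81.4,75.3,91.0
S13,104.1,86.0,111.2,108.5,108.0,97.3,103.8,102.7
S14,95.9,91.5,117.3,91.5,96.1,112.0,202.0,115.2
S15,119.4,108.2,107.4,128.1,112.6,114.2,112.1,114.6
S16,127.2,130.5,108.0,138.2,114.3,112.4,117.1,121.1
S17,128.7,80.3,106.5,134.3,119.5,119.5,113.6,114.6
S18,109.3,106.5,109.2,118.5,129.5,98.8,91.0,109.0
S19,125.1,114.5,101.0,130.7,109.8,107.3,104.2,113.2
S20,78.5,128.9,86.8,92.0,91.1,85.1,56.9,88.5
S21,73.2,1.5,20.7,44.3,59.4,149.5,186.0,76.4
S22,118.1,122.4,134.3,109.6,95.3,139.4,190.4,129.9
S23,75.0,ND,37.3,19.5,66.8,155.4,193.3,78.2
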