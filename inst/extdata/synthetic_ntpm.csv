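"gene","adipose","adrenal","brain","choroid_plexus","colon","fallopian_tube","heart","kidney","liver","lung","ovary","pancreas","pituitary","retina","skeletal_muscle","skin","spleen","testis"
"DRC1",0.5,1.2,7.6,11.4,0.7,6.5,0.8,0.3,0.6,15.9,0.8,1.9,1.1,7,0.6,1.1,1.4,10.7
"DRC2",0.6,0.8,4.3,3,0.7,11.7,0.6,0.5,0.7,3,0.4,1.1,0.6,10.7,0.7,0.5,0.4,3.2
"DRC4",0.4,0.7,3.1,7.7,0.9,7.2,0.2,1.2,0.6,4.3,0.6,1.1,0.6,13.7,0.7,0.6,0.8,7.2
"DRC8",0.6,0.5,16.4,16.6,1.1,11.2,1,0.8,0.5,11.1,1.3,0.6,0.8,5.2,1.6,2,0.3,29.2
"DRC12",0.6,1.1,1.7,4.5,0.6,4.7,0.4,0.4,0.5,5.5,0.6,0.6,0.4,4.9,1.1,0.6,0.6,3.8
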