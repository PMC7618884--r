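measure,group,mean,sd,n
theta,PD,92.65,13.21,12
theta,control,103.75,16.75,12
wmax,PD,127.86,29.77,12
wmax,control,160.19,36.49,12
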