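((t1:0.12,t2:0.07):0.05,(t3:0.09,t4:0.21):0.03);
((t1:0.30,t4:0.11):0.08,(t2:0.06,t3:0.16):0.12);
((t1:0.05,t3:0.05):0.20,(t2:0.05,t4:0.05):0.20);
(((t1:0.10,t2:0.04):0.06,t3:0.13):0.02,(t4:0.08,t5:0.19):0.07);
((t1:0.22,(t2:0.05,t5:0.09):0.04):0.11,(t3:0.07,t4:0.07):0.06);
(((t4:0.15,t5:0.02):0.03,t2:0.09):0.05,(t1:0.12,t3:0.18):0.04);
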