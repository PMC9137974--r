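sensor,counts,length_cm
l1M1,239,8.0
l2M1,330,5.3
l3M1,246,6.9
l1M2,265,13.0
l2M2,177,8.4
l1M3,252,7.8
l2M3,242,11.5
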