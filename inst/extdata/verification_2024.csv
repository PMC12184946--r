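village,age_group,abm,leslie,observed
Yunfeng,<=19,379,102,443
Yunfeng,20-30,98,238,73
Yunfeng,31-40,102,171,75
Yunfeng,41-59,302,324,300
Yunfeng,>=60,180,180,169
Shihan,<=19,183,180,195
Shihan,20-30,175,210,178
Shihan,31-40,112,200,159
Shihan,41-59,331,314,344
Shihan,>=60,523,450,443
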