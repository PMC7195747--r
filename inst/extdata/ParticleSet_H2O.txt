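# minimal single-particle set for test purposes
[Particle description]
# name mass charge volume color
H2O 18 0 30 blue

[Particle interactions]
pair 298
H2O_H2O 25
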