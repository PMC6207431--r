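category,sex,count
cancers,male,10481582
cancers,female,9476530
cardiovascular,male,16238344
cardiovascular,female,17210556
chronic_respiratory,male,2791652
chronic_respiratory,female,2595950
respiratory_infections,male,1138053
respiratory_infections,female,1303019
injuries_unintentional,male,2489142
injuries_unintentional,female,1348187
injuries_intentional,male,1545734
injuries_intentional,female,419983
other,male,8873696
other,female,9941748
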