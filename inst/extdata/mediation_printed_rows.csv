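factor,n_children,total_increase,nie,nde,proportion_printed
maternal_age,1919906,40.9,0.3,40.6,0.8
maternal_education,1908532,42.4,-0.2,42.5,-0.4
maternal_smoking,1712843,32.6,1.1,31.6,3.2
maternal_infection,1915368,41.6,0.0,41.6,0.0
mode_of_delivery,1919906,41.4,0.2,41.3,0.4
gestational_age,1915365,42.3,0.0,42.2,0.1
birth_weight,1912575,41.9,0.1,41.8,0.2
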