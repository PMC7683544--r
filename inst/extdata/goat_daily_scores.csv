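animal_id,d1_2,d2_3,d3_4,d4_5,d5_6,d6_7,d7_8,d8_9,index
Goat1,0.89,-5.64,-17.74,-2.22,-0.64,1.1,2.9,-4.19,-26.42
Goat2,-1.09,-2.14,-6.36,-1.34,6.2,-1.15,0.82,-2.69,-6.66
Goat3,-0.8,-1.24,-13.91,13.12,-4.39,1.41,-2.38,0.88,-6.51
Goat4,-0.72,-9.5,-1.31,0.84,4.06,-3.87,-1.53,-2.71,-4.01
Goat5,-0.27,-2.38,-6.83,5.64,-3.77,2.98,-1.53,1.19,-4.7
Goat6,-1.25,5.99,-5.78,0.6,-3.97,1.54,-0.99,-1.7,-4.31
Goat7,3.08,7.8,-1.11,-16.19,-14.88,4.89,-0.96,-4.08,-24.53
Goat8,0.7,-4.6,2.57,-3.76,5.77,-0.54,0.46,-3.67,-3.76
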