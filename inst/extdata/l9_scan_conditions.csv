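test,stage_color,rotation_angle,scanning_angle,mape
1,black,60,30,0.0407
2,black,45,45,0.0551
3,black,30,37,0.0269
4,red,60,37,0.0901
5,red,45,30,0.0811
6,red,30,45,0.1048
7,white,60,45,0.1826
8,white,45,37,0.0932
9,white,30,30,0.0913
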