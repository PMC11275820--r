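"name","x","y","z"
"ch1",6,0,0
"ch2",5.88471168241938,1.17054193209677,0
"ch3",5.54327719506772,2.29610059419054,0
"ch4",4.98881767381527,3.33342139811761,0
"ch5",4.24264068711929,4.24264068711928,0
"ch6",3.33342139811761,4.98881767381527,0
"ch7",2.29610059419054,5.54327719506772,0
"ch8",1.17054193209677,5.88471168241938,0
"ch9",3.67394039744206e-16,6,0
"ch10",-1.17054193209677,5.88471168241938,0
"ch11",-2.29610059419054,5.54327719506772,0
"ch12",-3.33342139811761,4.98881767381527,0
"ch13",-4.24264068711928,4.24264068711929,0
"ch14",-4.98881767381527,3.33342139811761,0
"ch15",-5.54327719506772,2.29610059419054,0
"ch16",-5.88471168241938,1.17054193209677,0
"ch17",-6,7.34788079488412e-16,0
"ch18",-5.88471168241938,-1.17054193209677,0
"ch19",-5.54327719506772,-2.29610059419054,0
"ch20",-4.98881767381527,-3.33342139811761,0
"ch21",-4.24264068711929,-4.24264068711928,0
"ch22",-3.33342139811761,-4.98881767381527,0
"ch23",-2.29610059419054,-5.54327719506772,0
"ch24",-1.17054193209677,-5.88471168241938,0
"ch25",-1.10218211923262e-15,-6,0
"ch26",1.17054193209677,-5.88471168241938,0
"ch27",2.29610059419054,-5.54327719506772,0
"ch28",3.33342139811761,-4.98881767381527,0
"ch29",4.24264068711928,-4.24264068711929,0
"ch30",4.98881767381527,-3.33342139811761,0
"ch31",5.54327719506772,-2.29610059419054,0
"ch32",5.88471168241938,-1.17054193209677,0
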