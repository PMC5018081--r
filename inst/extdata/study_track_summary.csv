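sample,crops,step_minutes,duration_hours,tracks,unbranched_tracks,spots
1,1,15,11.75,1,3,95
4,1,15,12.00,102,118,3753
5,1,15,17.25,5,9,474
6,1,15,18.00,10,14,707
11,5,15,16.25,249,281,8593
13,1,20,18.67,38,92,2262
14,1,20,18.00,47,77,1917
16,4,20,18.00,125,189,5295
17,4,20,17.67,47,69,2391
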