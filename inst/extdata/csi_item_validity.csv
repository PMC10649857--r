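item_round1,item_final,item_text,cvi,kappa,v,ci_lower,ci_upper
1,1,"Have you felt nervous, anxious or very upset?",0.900,0.900,0.900,0.833,0.942
4,2,"Have you ever had difficulty relaxing?",0.900,0.900,0.850,0.775,0.903
6,3,"Have you been easily annoyed or irritated?",0.933,0.933,0.875,0.804,0.923
7,4,"Have you been afraid as if something terrible would happen?",0.733,0.732,0.767,0.683,0.833
8,5,"Have you had little interest or pleasure in doing things?",0.833,0.833,0.817,0.738,0.876
9,6,"Have you ever felt discouraged, depressed or hopeless?",0.867,0.867,0.867,0.794,0.916
11,7,"Have you ever felt tired or low energy?",0.733,0.732,0.783,0.701,0.848
12,8,"Have you had no appetite or, on the contrary, have you eaten too much?",0.667,0.657,0.725,0.639,0.797
13,9,"Have you ever felt bad about yourself, felt that you are a failure or failing yourself?",0.800,0.800,0.817,0.738,0.876
14,10,"Have you had difficulty concentrating on doing everyday things, such as reading the newspaper or watching television?",0.867,0.867,0.800,0.720,0.862
16,11,"Have you ever had thoughts that you would be better off dead or harming yourself?",0.800,0.800,0.783,0.701,0.848
17,12,"Do familiar environments sometimes seem strange, confusing, threatening or unreal to you?",0.767,0.766,0.733,0.648,0.804
21,13,"Have you ever felt like you were not in control of your thoughts or ideas?",0.833,0.833,0.750,0.666,0.819
22,14,"Have you ever had difficulty following your conversation because you ramble or lose concentration too much when talking?",0.800,0.800,0.742,0.657,0.812
24,15,"Have you ever felt that other people are watching or talking about you?",0.800,0.800,0.767,0.683,0.833
25,16,"Have you occasionally noticed any sensation on or under the skin, such as bugs?",0.600,0.565,0.658,0.570,0.737
28,17,"Have you ever worried that something might go wrong in your mind?",0.667,0.657,0.717,0.630,0.790
30,18,"Have you ever felt confused about whether something that happened to you was real or imaginary?",0.733,0.732,0.725,0.639,0.797
34,19,"Have you ever had feelings of distrust towards other people?",0.800,0.800,0.758,0.674,0.826
35,20,"Have you ever seen unusual things such as flashes, flames, glaring lights or geometric shapes?",0.733,0.732,0.692,0.604,0.767
36,21,"Have you ever seen things that other people cannot see?",0.567,0.512,0.608,0.519,0.691
37,22,"Do you feel people find it difficult to understand your words?",0.633,0.614,0.650,0.561,0.729
41,23,"Have you ever had thoughts about your mind going faster than normal?",0.700,0.696,0.733,0.648,0.804
52,26,"In the last few days, have you felt that you were acting impulsively?",0.867,0.867,0.783,0.701,0.848
66,30,"Do you feel restless in classes or lectures if you have to listen to someone talk for a long time?",0.633,0.614,0.700,0.613,0.775
73,32,"Have you ever had chest pains?",0.700,0.696,0.708,0.622,0.782
76,34,"Have you ever felt your heart beating faster than usual?",0.800,0.800,0.800,0.720,0.862
77,35,"Have you ever felt short of breath?",0.767,0.766,0.775,0.692,0.841
82,36,"Have you had difficulty sleeping?",0.900,0.900,0.883,0.814,0.929
85,37,"Have you ever really had the idea of committing suicide?",0.833,0.833,0.792,0.711,0.855
86,38,"Have you thought about how you would carry it out?",0.800,0.800,0.775,0.692,0.841
87,39,"Have you ever tried to take your own life?",0.700,0.696,0.700,0.613,0.775
88,40,"Have you ever felt that you have difficulty maintaining your attention, are easily distracted, or cannot concentrate?",0.667,0.657,0.683,0.596,0.760
92,42,"Do you consider yourself a person with anger attacks that are difficult to predict?",0.867,0.867,0.783,0.701,0.848
97,43,"At any time, have you considered yourself to be a person who changes moods frequently?",0.833,0.833,0.767,0.683,0.833
100,45,"Have you ever felt people were dropping hints or saying things with a double meaning?",0.667,0.657,0.675,0.587,0.752
104,46,"Have you ever felt that people look at you strangely because of your appearance?",0.633,0.614,0.650,0.561,0.729
106,47,"Have you ever felt your thoughts were being pulled out of your head?",0.600,0.565,0.617,0.527,0.699
107,48,"Have you ever felt your thoughts were not your own?",0.733,0.732,0.708,0.622,0.782
109,49,"Have you ever felt your thoughts constantly repeated in your mind?",0.700,0.696,0.717,0.630,0.790
110,50,"Have you ever felt as if you were under the control of any external force or power?",0.600,0.565,0.592,0.502,0.675
112,51,"Have you ever heard voices when you were alone?",0.733,0.732,0.717,0.630,0.790
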