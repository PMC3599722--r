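id,time,status,age,male,income_gt40k,cpd,dep5min,motivation,confidence,sqa,MDM,HDM
1,0,1,24.554,1,0,22.13,1,10,9.293,0,0,1
1,1,1,24.554,1,0,22.13,1,10,9.293,0,0,1
1,2,1,24.554,1,0,22.13,1,10,9.293,0,0,1
1,3,1,24.554,1,0,22.13,1,10,9.293,0,0,1
1,4,0,24.554,1,0,22.13,1,10,9.293,0,0,1
2,0,1,64.513,0,1,21.894,0,6.576,1.466,0,0,0
2,1,1,64.513,0,1,21.894,0,6.576,1.466,0,0,0
2,2,1,64.513,0,1,21.894,0,6.576,1.466,0,0,0
2,3,1,64.513,0,1,21.894,0,6.576,1.466,0,0,0
2,4,1,64.513,0,1,21.894,0,6.576,1.466,0,0,0
3,0,1,24.378,1,0,25.394,1,6.411,4.279,0,0,0
3,1,1,24.378,1,0,25.394,1,6.411,4.279,0,0,0
3,2,,24.378,1,0,25.394,1,6.411,4.279,0,0,0
3,3,1,24.378,1,0,25.394,1,6.411,4.279,0,0,0
3,4,1,24.378,1,0,25.394,1,6.411,4.279,0,0,0
4,0,1,57.271,0,1,20.898,1,10,7.456,0,0,0
4,1,1,57.271,0,1,20.898,1,10,7.456,0,0,0
4,2,1,57.271,0,1,20.898,1,10,7.456,0,0,0
4,3,1,57.271,0,1,20.898,1,10,7.456,0,0,0
4,4,1,57.271,0,1,20.898,1,10,7.456,0,0,0
5,0,1,52.338,0,1,29.734,0,10,5.669,0,1,0
5,1,1,52.338,0,1,29.734,0,10,5.669,0,1,0
5,2,,52.338,0,1,29.734,0,10,5.669,0,1,0
5,3,,52.338,0,1,29.734,0,10,5.669,0,1,0
5,4,0,52.338,0,1,29.734,0,10,5.669,0,1,0
6,0,1,66.978,1,0,22.18,1,7.827,4.138,0,0,0
6,1,1,66.978,1,0,22.18,1,7.827,4.138,0,0,0
6,2,1,66.978,1,0,22.18,1,7.827,4.138,0,0,0
6,3,1,66.978,1,0,22.18,1,7.827,4.138,0,0,0
6,4,1,66.978,1,0,22.18,1,7.827,4.138,0,0,0
7,0,1,43.871,1,0,23.037,0,8.59,8.488,0,0,0
7,1,1,43.871,1,0,23.037,0,8.59,8.488,0,0,0
7,2,1,43.871,1,0,23.037,0,8.59,8.488,0,0,0
7,3,1,43.871,1,0,23.037,0,8.59,8.488,0,0,0
7,4,1,43.871,1,0,23.037,0,8.59,8.488,0,0,0
8,0,1,48.353,1,0,33.628,0,9.072,9.021,0,1,0
8,1,1,48.353,1,0,33.628,0,9.072,9.021,0,1,0
8,2,1,48.353,1,0,33.628,0,9.072,9.021,0,1,0
8,3,1,48.353,1,0,33.628,0,9.072,9.021,0,1,0
8,4,1,48.353,1,0,33.628,0,9.072,9.021,0,1,0
9,0,1,40.873,1,1,20.155,1,8.367,7.725,1,0,1
9,1,1,40.873,1,1,20.155,1,8.367,7.725,1,0,1
9,2,0,40.873,1,1,20.155,1,8.367,7.725,1,0,1
9,3,0,40.873,1,1,20.155,1,8.367,7.725,1,0,1
9,4,1,40.873,1,1,20.155,1,8.367,7.725,1,0,1
10,0,1,56.421,1,0,27.006,1,9.491,7.815,1,0,1
10,1,0,56.421,1,0,27.006,1,9.491,7.815,1,0,1
10,2,0,56.421,1,0,27.006,1,9.491,7.815,1,0,1
10,3,1,56.421,1,0,27.006,1,9.491,7.815,1,0,1
10,4,1,56.421,1,0,27.006,1,9.491,7.815,1,0,1
11,0,1,47.018,0,1,20.822,0,8.305,4.068,0,0,1
11,1,1,47.018,0,1,20.822,0,8.305,4.068,0,0,1
11,2,1,47.018,0,1,20.822,0,8.305,4.068,0,0,1
11,3,1,47.018,0,1,20.822,0,8.305,4.068,0,0,1
11,4,1,47.018,0,1,20.822,0,8.305,4.068,0,0,1
12,0,1,40.625,1,0,25.808,1,9.547,5.265,1,0,0
12,1,0,40.625,1,0,25.808,1,9.547,5.265,1,0,0
12,2,,40.625,1,0,25.808,1,9.547,5.265,1,0,0
12,3,,40.625,1,0,25.808,1,9.547,5.265,1,0,0
12,4,,40.625,1,0,25.808,1,9.547,5.265,1,0,0
13,0,1,45.709,0,1,21.046,0,2.648,1.488,0,0,1
13,1,1,45.709,0,1,21.046,0,2.648,1.488,0,0,1
13,2,1,45.709,0,1,21.046,0,2.648,1.488,0,0,1
13,3,1,45.709,0,1,21.046,0,2.648,1.488,0,0,1
13,4,1,45.709,0,1,21.046,0,2.648,1.488,0,0,1
14,0,1,42.157,0,0,24.972,0,7.317,5.99,0,1,0
14,1,1,42.157,0,0,24.972,0,7.317,5.99,0,1,0
14,2,1,42.157,0,0,24.972,0,7.317,5.99,0,1,0
14,3,1,42.157,0,0,24.972,0,7.317,5.99,0,1,0
14,4,1,42.157,0,0,24.972,0,7.317,5.99,0,1,0
15,0,1,49.148,1,0,28.291,0,9.073,5.491,1,1,0
15,1,1,49.148,1,0,28.291,0,9.073,5.491,1,1,0
15,2,0,49.148,1,0,28.291,0,9.073,5.491,1,1,0
15,3,0,49.148,1,0,28.291,0,9.073,5.491,1,1,0
15,4,0,49.148,1,0,28.291,0,9.073,5.491,1,1,0
16,0,1,57.992,0,1,40.482,1,7.681,10,1,0,0
16,1,1,57.992,0,1,40.482,1,7.681,10,1,0,0
16,2,1,57.992,0,1,40.482,1,7.681,10,1,0,0
16,3,1,57.992,0,1,40.482,1,7.681,10,1,0,0
16,4,1,57.992,0,1,40.482,1,7.681,10,1,0,0
17,0,1,40.7,0,1,25.889,0,7.453,7.823,0,0,0
17,1,1,40.7,0,1,25.889,0,7.453,7.823,0,0,0
17,2,1,40.7,0,1,25.889,0,7.453,7.823,0,0,0
17,3,,40.7,0,1,25.889,0,7.453,7.823,0,0,0
17,4,,40.7,0,1,25.889,0,7.453,7.823,0,0,0
18,0,1,57.5,0,0,23.457,1,9.155,8.38,0,1,0
18,1,1,57.5,0,0,23.457,1,9.155,8.38,0,1,0
18,2,,57.5,0,0,23.457,1,9.155,8.38,0,1,0
18,3,,57.5,0,0,23.457,1,9.155,8.38,0,1,0
18,4,1,57.5,0,0,23.457,1,9.155,8.38,0,1,0
19,0,1,60.258,1,0,27.575,1,8.637,6.167,0,0,1
19,1,1,60.258,1,0,27.575,1,8.637,6.167,0,0,1
19,2,1,60.258,1,0,27.575,1,8.637,6.167,0,0,1
19,3,1,60.258,1,0,27.575,1,8.637,6.167,0,0,1
19,4,1,60.258,1,0,27.575,1,8.637,6.167,0,0,1
20,0,1,43.231,0,0,11.546,0,10,8.04,0,0,1
20,1,0,43.231,0,0,11.546,0,10,8.04,0,0,1
20,2,1,43.231,0,0,11.546,0,10,8.04,0,0,1
20,3,1,43.231,0,0,11.546,0,10,8.04,0,0,1
20,4,1,43.231,0,0,11.546,0,10,8.04,0,0,1
21,0,1,53.969,1,1,44.912,0,7.281,10,0,0,1
21,1,1,53.969,1,1,44.912,0,7.281,10,0,0,1
21,2,1,53.969,1,1,44.912,0,7.281,10,0,0,1
21,3,1,53.969,1,1,44.912,0,7.281,10,0,0,1
21,4,1,53.969,1,1,44.912,0,7.281,10,0,0,1
22,0,1,26.843,0,0,33.653,0,10,6.592,0,1,0
22,1,1,26.843,0,0,33.653,0,10,6.592,0,1,0
22,2,1,26.843,0,0,33.653,0,10,6.592,0,1,0
22,3,0,26.843,0,0,33.653,0,10,6.592,0,1,0
22,4,0,26.843,0,0,33.653,0,10,6.592,0,1,0
23,0,1,47.59,0,0,29.94,0,10,4.824,0,0,0
23,1,1,47.59,0,0,29.94,0,10,4.824,0,0,0
23,2,1,47.59,0,0,29.94,0,10,4.824,0,0,0
23,3,0,47.59,0,0,29.94,0,10,4.824,0,0,0
23,4,0,47.59,0,0,29.94,0,10,4.824,0,0,0
24,0,1,31.334,1,0,21.301,1,7.267,5.524,0,1,0
24,1,1,31.334,1,0,21.301,1,7.267,5.524,0,1,0
24,2,1,31.334,1,0,21.301,1,7.267,5.524,0,1,0
24,3,1,31.334,1,0,21.301,1,7.267,5.524,0,1,0
24,4,1,31.334,1,0,21.301,1,7.267,5.524,0,1,0
25,0,1,14.482,1,0,28.127,0,8.779,2.462,0,1,0
25,1,,14.482,1,0,28.127,0,8.779,2.462,0,1,0
25,2,,14.482,1,0,28.127,0,8.779,2.462,0,1,0
25,3,0,14.482,1,0,28.127,0,8.779,2.462,0,1,0
25,4,0,14.482,1,0,28.127,0,8.779,2.462,0,1,0
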