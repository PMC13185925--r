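"family_id","zygosity","twin","pgs","exposure","med_01","med_02","med_03","med_04","med_05","med_06","outcome"
1,"MZ",1,0.943011169165157,0,0.4,0.4,3,4,4,2.2,0.333333333333333
1,"MZ",2,0.943011169165157,0,3.2,1,0,2,3.6,1.2,0.666666666666667
2,"MZ",1,-0.28311284733735,0.375,2,3.8,4,2.6,4,3.8,3.16666666666667
2,"MZ",2,-0.28311284733735,0.875,0.2,3.8,0,1,4,0.6,2.16666666666667
3,"MZ",1,0.379197287254554,0,2.8,1.2,0.2,1,1.6,1.4,0.5
3,"MZ",2,0.379197287254554,0,0,1.4,0,1.75,2.4,3.2,0.833333333333333
4,"MZ",1,0.0139240543456968,1.625,1,2.8,1.4,3,3,4,2.66666666666667
4,"MZ",2,0.0139240543456968,0.5,3.25,2.8,3.2,4,3,4,0.166666666666667
5,"MZ",1,1.14234122168161,1.75,0.2,0.8,0,1,2,0,0.4
5,"MZ",2,1.14234122168161,0,0.25,1.2,2.4,3.25,4,3.2,2
6,"MZ",1,-0.448255358832852,0,4,2.6,1.8,0.4,2.4,2.2,0
6,"MZ",2,-0.448255358832852,0.5,2.2,3.2,2.8,2.5,2.8,4,0
7,"MZ",1,-2.50555697302119,0,1.8,1,0.75,2.4,0.2,1.4,0
7,"MZ",2,-2.50555697302119,0,0.2,0,2,3.8,0.6,0.4,1.66666666666667
8,"MZ",1,1.26846119920938,2.25,0.8,0.4,1,1.4,2.2,0.2,2
8,"MZ",2,1.26846119920938,0,0.6,1.4,0,2.75,3.6,3.2,3.6
9,"MZ",1,-0.347047430760372,1,1,2.2,3.2,2.8,3.2,2.25,4
9,"MZ",2,-0.347047430760372,1.125,3.8,3,3.6,3.4,4,3.6,4
10,"MZ",1,1.03074243617236,0,1.6,2,2.2,1.2,2,0.6,0
10,"MZ",2,1.03074243617236,0,0.4,0,2,0.2,0,2.2,0
11,"MZ",1,0.0728083480758206,0,2.2,0,0.25,4,1.6,0,0
11,"MZ",2,0.0728083480758206,0,2.2,0,0,0.6,0,0.2,0
12,"MZ",1,1.0914696642416,1.875,2.4,2.6,0,2.6,2.5,2,0.166666666666667
12,"MZ",2,1.0914696642416,0.375,2.4,1,0,2.6,3,2.4,0
13,"DZss",1,-1.35346116787699,0,0,0,1.2,1.4,2.2,1.8,0.5
13,"DZss",2,-0.39922017547088,0.75,1.6,2.8,3.6,1.8,0.2,3.4,0.333333333333333
14,"DZss",1,0.224141775862644,1.375,3.5,2.6,3.8,2.2,3,2.8,0
14,"DZss",2,-0.192449617139683,2,2.5,1.8,1.8,2,1.25,0.6,1.5
15,"DZss",1,0.0170765272556255,3.125,0.8,0.6,1.2,0.4,1,0.4,0
15,"DZss",2,-1.21439125802189,3.625,3,3.6,3.6,3.6,2.4,4,1.16666666666667
16,"DZss",1,0.141892926444977,0.125,0.2,0.75,0,0,1.6,0.6,0
16,"DZss",2,0.834755744547165,0,0.6,0,1.5,0.2,0,0,0
17,"DZss",1,0.150822060176129,0,1,0.6,3.2,0,0,0,0.6
17,"DZss",2,1.76381411997839,0.125,1.8,3,3,0.2,1.6,3,2.16666666666667
18,"DZss",1,-1.10260849713877,0,1.6,1.2,2.6,2.4,1.6,1.2,0.5
18,"DZss",2,-0.912172327246998,0.125,0,1,1.2,4,4,3.6,0
19,"DZss",1,-1.19798658544637,0.5,1,2.8,1.2,0,2.6,2,0
19,"DZss",2,1.20342005882003,2.25,2.4,3.8,1.4,3,3.8,4,2.33333333333333
20,"DZos",1,0.493559352442265,1.5,0.25,0.8,0.6,0.6,2.8,0,0.5
20,"DZos",2,-0.432339992972117,0.375,3.2,2.6,0.5,1.2,2,1.4,0
21,"DZos",1,-0.36386407860369,0,1.2,2.8,3.6,1.75,2.2,0.6,1.66666666666667
21,"DZos",2,0.642488638033168,1.25,4,3.2,2.6,1.6,0.2,3.75,3.16666666666667
22,"DZos",1,0.581266544235576,0.5,1.8,0,2,2.8,2.8,0.4,0
22,"DZos",2,-0.0256922366843879,0.125,0.2,2.8,0.6,2.4,0.8,0,0
23,"DZos",1,-0.604355682044205,1.71428571428571,2.4,2.8,0.8,2.4,0.6,1.2,0
23,"DZos",2,0.673377232353785,2.75,3.2,3,2,1.8,3.2,3.6,1
24,"DZos",1,0.592318342656401,0,2,3.8,2,2,3.4,1.4,0.166666666666667
24,"DZos",2,0.127943662599192,1.25,0,4,3.4,3.8,3.8,3.8,2
25,"DZos",1,-1.57543537556035,0,0.6,2.8,1.8,2.6,0.2,3.8,0.5
25,"DZos",2,-1.98074138024709,0.375,0.6,1.4,0.4,1.8,2,1.6,0
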