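"cell_id","layer","z","area_um2","neighbour_ids","nuclear_area_um2","interior"
"1",0,0.0833,34.963,"6;10;11;14;15;23",19.095,TRUE
"2",0,0.0833,37.531,"5;7;10;13;17;20",19.647,TRUE
"3",0,0.0833,21.333,"8;12;14;17;22",10.316,TRUE
"4",0,0.0833,33.975,"7;9;11;18;20;21;24",18.624,TRUE
"5",0,0.0833,12.049,"2;7;12;13;19",0,TRUE
"6",0,0.0833,17.778,"1;10;12;19",11.815,TRUE
"7",0,0.0833,36.543,"2;4;5;16;19;24",19.637,TRUE
"8",0,0.0833,18.765,"3;14;17;20;21",0,TRUE
"9",0,0.0833,8.099,"4;14;15;16;21",0,TRUE
"10",0,0.0833,25.679,"1;2;6;12;15;17",6.408,TRUE
"11",0,0.0833,35.16,"1;4;18;19;22;23;24",19.072,TRUE
"12",0,0.0833,23.309,"3;5;6;10;13;19;22",5.173,TRUE
"13",0,0.0833,9.086,"2;5;12;18;20",0,TRUE
"14",0,0.0833,38.519,"1;3;8;9;15;21;22;23",20.048,TRUE
"15",0,0.0833,25.086,"1;9;10;14;16",12.962,TRUE
"16",0,0.0833,9.877,"7;9;15",0,TRUE
"17",0,0.0833,36.346,"2;3;8;10;20",19.434,TRUE
"18",0,0.0833,17.58,"4;11;13;20;22",0,TRUE
"19",0,0.0833,13.235,"5;6;7;11;12;24",0,TRUE
"20",0,0.0833,30.617,"2;4;8;13;17;18;21",17.462,TRUE
"21",0,0.0833,17.185,"4;8;9;14;20",0,TRUE
"22",0,0.0833,32.198,"3;11;12;14;18;23",17.94,TRUE
"23",0,0.0833,15.605,"1;11;14;22",0,TRUE
"24",0,0.0833,25.481,"4;7;11;19",15.406,TRUE
"1",1,0.25,31.802,"6;10;11;14;15;19;23",31.802,TRUE
"2",1,0.25,36.148,"5;7;10;13;17;20",36.148,TRUE
"3",1,0.25,24.099,"12;14;17;22",24.099,TRUE
"4",1,0.25,31.21,"9;11;16;18;20;21;24",31.21,TRUE
"5",1,0.25,15.605,"2;7;12;13;19",13.839,TRUE
"6",1,0.25,12.049,"1;10;12;19",12.049,TRUE
"7",1,0.25,33.58,"2;5;16;19;24",33.58,TRUE
"8",1,0.25,13.037,"14;17;20;21",3.081,TRUE
"9",1,0.25,17.975,"4;14;15;16;21",17.975,TRUE
"10",1,0.25,36.938,"1;2;6;12;15;16;17",36.938,TRUE
"11",1,0.25,32.198,"1;4;19;22;23;24",32.198,TRUE
"12",1,0.25,35.753,"3;5;6;10;13;19;22",35.753,TRUE
"13",1,0.25,5.531,"2;5;12;18;20",0,TRUE
"14",1,0.25,35.16,"1;3;8;9;15;21;22;23",35.16,TRUE
"15",1,0.25,26.074,"1;9;10;14;16",26.074,TRUE
"16",1,0.25,19.358,"4;7;9;10;15",19.358,TRUE
"17",1,0.25,32.988,"2;3;8;10;20",32.988,TRUE
"18",1,0.25,9.877,"4;13;20;22",0,TRUE
"19",1,0.25,24.889,"1;5;6;7;11;12;24",24.889,TRUE
"20",1,0.25,27.457,"2;4;8;13;17;18;21",27.457,TRUE
"21",1,0.25,14.222,"4;8;9;14;20",6.552,TRUE
"22",1,0.25,29.037,"3;11;12;14;18;23",29.037,TRUE
"23",1,0.25,9.284,"1;11;14;22",0,TRUE
"24",1,0.25,21.728,"4;7;11;19",21.728,TRUE
"1",2,0.4167,25.481,"6;10;11;14;15;19;23",25.481,TRUE
"2",2,0.4167,31.21,"5;7;10;13;16;17;20",31.21,TRUE
"3",2,0.4167,17.778,"8;12;14;17;22",17.778,TRUE
"4",2,0.4167,23.506,"7;9;11;16;18;20;21;24",23.506,TRUE
"5",2,0.4167,28.444,"2;7;12;13;19",28.444,TRUE
"6",2,0.4167,2.568,"1;10;12;19",0,TRUE
"7",2,0.4167,27.654,"2;4;5;16;19;24",27.654,TRUE
"8",2,0.4167,34.765,"3;14;17;20;21",34.765,TRUE
"9",2,0.4167,20.741,"4;14;15;16;21",20.741,TRUE
"10",2,0.4167,39.901,"1;2;6;12;15;16;17",39.901,TRUE
"11",2,0.4167,25.284,"1;4;18;19;22;23;24",25.284,TRUE
"12",2,0.4167,38.321,"3;5;6;10;13;17;19;22",38.321,TRUE
"13",2,0.4167,21.136,"2;5;12;18;20;22",21.136,TRUE
"14",2,0.4167,29.432,"1;3;8;9;15;21;22;23",29.432,TRUE
"15",2,0.4167,19.951,"1;9;10;14;16",19.951,TRUE
"16",2,0.4167,25.284,"2;4;7;9;10;15",25.284,TRUE
"17",2,0.4167,26.667,"2;3;8;10;12",26.667,TRUE
"18",2,0.4167,13.235,"4;11;13;20;22",5.297,TRUE
"19",2,0.4167,32.395,"1;5;6;7;11;12;24",32.395,TRUE
"20",2,0.4167,18.963,"2;4;8;13;18;21",18.963,TRUE
"21",2,0.4167,33.778,"4;8;9;14;20",33.778,TRUE
"22",2,0.4167,20.543,"3;11;12;13;14;18;23",20.543,TRUE
"23",2,0.4167,8.889,"1;11;14;22",0,TRUE
"24",2,0.4167,10.074,"4;7;11;19",8.852,TRUE
"1",3,0.5833,12.049,"6;10;15;19;23",0,TRUE
"2",3,0.5833,15.605,"5;7;10;13;16;17;20",1.473,TRUE
"3",3,0.5833,8.099,"8;12;17;22",0,TRUE
"4",3,0.5833,10.864,"7;11;18;21;24",0,TRUE
"5",3,0.5833,36.741,"2;7;12;13;19",25.974,TRUE
"6",3,0.5833,3.753,"1;10;12;19",0,TRUE
"7",3,0.5833,13.037,"2;4;5;16;19;24",0,TRUE
"8",3,0.5833,63.012,"3;14;17;20;21;22;23",45.757,TRUE
"9",3,0.5833,10.469,"14;15;16;21",2.999,TRUE
"10",3,0.5833,41.481,"1;2;6;12;15;16;17",24.206,TRUE
"11",3,0.5833,11.654,"4;18;19;23;24",0,TRUE
"12",3,0.5833,38.123,"3;5;6;10;13;17;18;19",22.124,TRUE
"13",3,0.5833,34.765,"2;5;12;18;20",26.57,TRUE
"14",3,0.5833,13.235,"8;9;15;21;23",0,TRUE
"15",3,0.5833,9.284,"1;9;10;14;16",0,TRUE
"16",3,0.5833,20.938,"2;7;9;10;15",12.127,TRUE
"17",3,0.5833,12.049,"2;3;8;10;12",0,TRUE
"18",3,0.5833,53.728,"4;11;12;13;20;21;22;23",37.872,TRUE
"19",3,0.5833,35.16,"1;5;6;7;11;12;23;24",22.686,TRUE
"20",3,0.5833,9.086,"2;8;13;18;21",0,TRUE
"21",3,0.5833,58.864,"4;8;9;14;18;20",42.47,TRUE
"22",3,0.5833,10.074,"3;8;18;23",0,TRUE
"23",3,0.5833,47.012,"1;8;11;14;18;19;22",33.271,TRUE
"24",3,0.5833,6.914,"4;7;11;19",0,TRUE
"1",4,0.75,16.79,"6;10;15;19;23",0,TRUE
"2",4,0.75,20.346,"5;7;10;13;16;17;20",0,TRUE
"3",4,0.75,11.062,"8;12;17;22",0,TRUE
"4",4,0.75,15.407,"7;11;16;18;21;24",0,TRUE
"5",4,0.75,15.012,"2;7;12;13;19",0,TRUE
"6",4,0.75,5.333,"1;12;19",0,TRUE
"7",4,0.75,17.975,"2;4;5;16;19;24",0,TRUE
"8",4,0.75,61.037,"3;14;17;20;21;22;23",26.189,TRUE
"9",4,0.75,10.074,"14;15;16;21",0,TRUE
"10",4,0.75,23.506,"1;2;12;15;16;17",0,TRUE
"11",4,0.75,16.593,"4;18;19;23;24",0,TRUE
"12",4,0.75,22.123,"3;5;6;10;13;18;19",0,TRUE
"13",4,0.75,13.037,"2;5;12;18;20",0.93,TRUE
"14",4,0.75,18.37,"8;9;21;23",0,TRUE
"15",4,0.75,13.037,"1;9;10;16;23",0,TRUE
"16",4,0.75,12.247,"2;4;7;9;10;15",0,TRUE
"17",4,0.75,17.383,"2;3;8;10",0,TRUE
"18",4,0.75,84.938,"4;11;12;13;20;21;22;23",43.176,TRUE
"19",4,0.75,17.185,"1;5;6;7;11;12;23;24",0,TRUE
"20",4,0.75,13.037,"2;8;13;18;21",0,TRUE
"21",4,0.75,49.58,"4;8;9;14;18;20",19.523,TRUE
"22",4,0.75,14.025,"3;8;18;23",0,TRUE
"23",4,0.75,78.025,"1;8;11;14;15;18;19;22",40.416,TRUE
"24",4,0.75,9.877,"4;7;11;19",0,TRUE
"1",5,0.9167,21.333,"6;10;15;19;23",0,TRUE
"2",5,0.9167,25.481,"5;7;10;13;16;17;20",0,TRUE
"3",5,0.9167,15.012,"8;12;14;17;22",0,TRUE
"4",5,0.9167,19.951,"7;9;11;16;18;21;24",0,TRUE
"5",5,0.9167,19.556,"2;7;12;13;19",0,TRUE
"6",5,0.9167,6.321,"1;12;19",0,TRUE
"7",5,0.9167,22.519,"2;4;5;16;19;24",0,TRUE
"8",5,0.9167,29.827,"3;14;17;20;21",0,TRUE
"9",5,0.9167,13.037,"4;14;15;16;21",0,TRUE
"10",5,0.9167,30.222,"1;2;12;15;16;17",0,TRUE
"11",5,0.9167,21.333,"4;18;19;23;24",0,TRUE
"12",5,0.9167,28.247,"3;5;6;10;13;18;19;22",0,TRUE
"13",5,0.9167,14.815,"2;5;12;18;20",0,TRUE
"14",5,0.9167,24.296,"3;8;9;21;22;23",0,TRUE
"15",5,0.9167,16.198,"1;9;10;16;23",0,TRUE
"16",5,0.9167,15.802,"2;4;7;9;10;15",0,TRUE
"17",5,0.9167,22.716,"2;3;8;10;20",0,TRUE
"18",5,0.9167,67.753,"4;11;12;13;20;21;22;23",21.21,TRUE
"19",5,0.9167,21.926,"1;5;6;7;11;12;24",0,TRUE
"20",5,0.9167,17.58,"2;8;13;17;18;21",0,TRUE
"21",5,0.9167,28.049,"4;8;9;14;18;20",0,TRUE
"22",5,0.9167,18.37,"3;12;14;18;23",0,TRUE
"23",5,0.9167,63.012,"1;11;14;15;18;22",20.29,TRUE
"24",5,0.9167,12.642,"4;7;11;19",0,TRUE
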