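id,gender,age,hypertension,heart_disease,ever_married,work_type,Residence_type,avg_glucose_level,bmi,smoking_status,stroke
1,Male,75,0,1,No,Private,Rural,99.71,34.6,Unknown,0
2,Female,33,0,0,Yes,Private,Rural,84.97,35.3,never smoked,0
3,Female,53,0,0,No,Private,Urban,182.38,31.2,formerly smoked,0
4,Male,59,0,0,Yes,Private,Rural,70.64,15.5,never smoked,0
5,Male,54,0,0,Yes,Private,Rural,100.57,28.1,Unknown,0
6,Female,43,0,0,Yes,Private,Urban,88.52,36,Unknown,0
7,Female,78,1,0,No,Private,Urban,102.31,34.2,formerly smoked,0
8,Female,43,1,0,Yes,Private,Urban,87.31,27.2,never smoked,0
9,Female,89,0,0,Yes,Private,Urban,78.83,12,Unknown,1
10,Female,44,0,0,Yes,Govt_job,Urban,117,28.9,Unknown,0
11,Male,74,1,0,Yes,Private,Urban,86.56,32.5,Unknown,0
12,Female,90,0,0,Yes,Private,Rural,168.1,28.8,Unknown,1
13,Female,14,0,0,No,children,Urban,180.05,29.6,formerly smoked,0
14,Male,39,1,0,Yes,Private,Urban,82.68,31.5,never smoked,0
15,Male,42,0,0,Yes,Private,Rural,86.61,N/A,formerly smoked,0
16,Male,59,0,0,Yes,Self-employed,Rural,84.18,37.7,smokes,0
17,Female,39,0,0,Yes,Private,Urban,118.97,31.8,never smoked,0
18,Female,1,0,0,No,children,Urban,91.54,19.8,never smoked,0
19,Male,1,0,0,No,children,Urban,96.88,38.2,Unknown,0
20,Male,74,0,0,No,Private,Rural,73.15,36.9,never smoked,0
21,Male,38,0,0,Yes,Self-employed,Urban,77.42,34.3,Unknown,0
22,Female,6,0,0,No,children,Rural,181.68,16.9,Unknown,0
23,Female,41,0,0,Yes,Private,Rural,117.17,24.5,never smoked,0
24,Female,72,0,0,No,Govt_job,Rural,116.98,32.9,formerly smoked,0
25,Male,87,0,0,Yes,Private,Urban,147.46,28.8,never smoked,0
26,Male,36,0,0,Yes,Private,Urban,151.98,30.9,formerly smoked,0
27,Male,39,0,0,Yes,Self-employed,Rural,112.34,45.7,N/A,0
28,Male,6,0,0,No,children,Urban,91.47,22.8,Unknown,0
29,Female,55,0,0,Yes,Govt_job,Urban,106.07,13.7,formerly smoked,0
30,Female,31,0,0,Yes,Govt_job,Rural,72.57,30.4,Unknown,0
31,Male,55,0,0,Yes,Private,Rural,70.08,23.7,never smoked,0
32,Male,61,0,0,Yes,Self-employed,Rural,92.98,31.6,never smoked,0
33,Male,68,0,0,Yes,Private,Rural,177.16,22.8,never smoked,0
34,Female,32,0,0,Yes,Private,Rural,173.32,44,never smoked,0
35,Female,56,0,0,No,Govt_job,Urban,117.95,27.6,Unknown,0
36,Female,7,0,0,No,children,Rural,71.32,25.2,formerly smoked,0
37,Female,28,0,0,Yes,Private,Urban,77.23,27.3,never smoked,0
38,Female,26,0,0,No,Private,Rural,92.93,34.5,Unknown,0
39,Male,1,0,0,No,children,Urban,71.65,N/A,smokes,0
40,Male,46,0,0,Yes,Private,Urban,84.33,17.1,formerly smoked,0
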