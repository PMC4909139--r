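"sex","age_months","L","M","S"
"male",0,1,50,0.04
"male",1,1,51,0.04
"male",2,1,51.99,0.04
"male",3,1,52.96,0.04
"male",4,1,53.94,0.04
"male",5,1,54.91,0.04
"male",6,1,55.87,0.04
"male",7,1,56.83,0.04
"male",8,1,57.79,0.04
"male",9,1,58.75,0.04
"male",10,1,59.71,0.04
"male",11,1,60.66,0.04
"male",12,1,61.61,0.04
"male",13,1,62.56,0.04
"male",14,1,63.51,0.04
"male",15,1,64.46,0.04
"male",16,1,65.41,0.04
"male",17,1,66.35,0.04
"male",18,1,67.3,0.04
"male",19,1,68.24,0.04
"male",20,1,69.18,0.04
"male",21,1,70.12,0.04
"male",22,1,71.06,0.04
"male",23,1,72,0.04
"male",24,1,72.93,0.04
"male",25,1,73.87,0.04
"male",26,1,74.81,0.04
"male",27,1,75.74,0.04
"male",28,1,76.67,0.04
"male",29,1,77.61,0.04
"male",30,1,78.54,0.04
"male",31,1,79.47,0.04
"male",32,1,80.4,0.04
"male",33,1,81.33,0.04
"male",34,1,82.26,0.04
"male",35,1,83.19,0.04
"male",36,1,84.11,0.04
"male",37,1,85.04,0.04
"male",38,1,85.97,0.04
"male",39,1,86.89,0.04
"male",40,1,87.82,0.04
"male",41,1,88.74,0.04
"male",42,1,89.67,0.04
"male",43,1,90.59,0.04
"male",44,1,91.51,0.04
"male",45,1,92.43,0.04
"male",46,1,93.35,0.04
"male",47,1,94.27,0.04
"male",48,1,95.19,0.04
"male",49,1,96.11,0.04
"male",50,1,97.03,0.04
"male",51,1,97.95,0.04
"male",52,1,98.87,0.04
"male",53,1,99.79,0.04
"male",54,1,100.7,0.04
"male",55,1,101.62,0.04
"male",56,1,102.54,0.04
"male",57,1,103.45,0.04
"male",58,1,104.37,0.04
"male",59,1,105.28,0.04
"female",0,1,49.2,0.04
"female",1,1,50.18,0.04
"female",2,1,51.15,0.04
"female",3,1,52.1,0.04
"female",4,1,53.06,0.04
"female",5,1,54.01,0.04
"female",6,1,54.95,0.04
"female",7,1,55.89,0.04
"female",8,1,56.83,0.04
"female",9,1,57.77,0.04
"female",10,1,58.71,0.04
"female",11,1,59.64,0.04
"female",12,1,60.57,0.04
"female",13,1,61.5,0.04
"female",14,1,62.43,0.04
"female",15,1,63.36,0.04
"female",16,1,64.29,0.04
"female",17,1,65.21,0.04
"female",18,1,66.14,0.04
"female",19,1,67.06,0.04
"female",20,1,67.98,0.04
"female",21,1,68.9,0.04
"female",22,1,69.82,0.04
"female",23,1,70.74,0.04
"female",24,1,71.65,0.04
"female",25,1,72.57,0.04
"female",26,1,73.49,0.04
"female",27,1,74.4,0.04
"female",28,1,75.31,0.04
"female",29,1,76.23,0.04
"female",30,1,77.14,0.04
"female",31,1,78.05,0.04
"female",32,1,78.96,0.04
"female",33,1,79.87,0.04
"female",34,1,80.78,0.04
"female",35,1,81.69,0.04
"female",36,1,82.59,0.04
"female",37,1,83.5,0.04
"female",38,1,84.41,0.04
"female",39,1,85.31,0.04
"female",40,1,86.22,0.04
"female",41,1,87.12,0.04
"female",42,1,88.03,0.04
"female",43,1,88.93,0.04
"female",44,1,89.83,0.04
"female",45,1,90.73,0.04
"female",46,1,91.63,0.04
"female",47,1,92.53,0.04
"female",48,1,93.43,0.04
"female",49,1,94.33,0.04
"female",50,1,95.23,0.04
"female",51,1,96.13,0.04
"female",52,1,97.03,0.04
"female",53,1,97.93,0.04
"female",54,1,98.82,0.04
"female",55,1,99.72,0.04
"female",56,1,100.62,0.04
"female",57,1,101.51,0.04
"female",58,1,102.41,0.04
"female",59,1,103.3,0.04
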