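"from","to","d_gain","r_gain","d_loss","r_loss"
"FL","IFL",-0.12,-0.92,-0.07,-0.88
"FL","CL",-0.04,-0.24,-0.02,-0.13
"FL","O",-2.1,-0.99,-0.1,-0.83
"FL","CoL",-0.28,-0.58,0.17,5.67
"FL","W",0.02,2,0.03,0
"IFL","FL",9.99,1.29,9.01,1.04
"IFL","CL",0.11,0.44,-4.79,-0.93
"IFL","O",-3.07,-0.98,-3.85,-0.98
"IFL","CoL",0,0,-0.29,-0.29
"IFL","W",-0.01,-0.5,-0.06,-0.86
"CL","FL",-7.03,-0.82,-4.61,-0.74
"CL","IFL",0.2,0.91,-1.59,-0.79
"CL","O",5.45,1.56,6.16,2.21
"CL","CoL",0.06,0.08,0.14,0.2
"CL","W",-0.01,-0.5,-0.04,-0.8
"O","FL",-2.33,-1,-0.23,-1
"O","IFL",-0.06,-1,-0.07,-1
"O","CL",-0.05,-0.71,-0.12,-0.86
"O","CoL",0.21,0.95,0.4,13.33
"O","W",0,0,0,0
"CoL","FL",-0.59,-1,-0.01,-1
"CoL","IFL",-0.02,-1,0,0
"CoL","CL",-0.01,-0.5,0,0
"CoL","O",-0.24,-1,-0.01,-1
"CoL","W",0,0,0,0
"W","FL",-0.04,-0.5,0.02,1
"W","IFL",0.01,0,0,0
"W","CL",0,0,-0.01,1
"W","O",-0.03,-1,-0.01,-1
"W","CoL",-0.01,-1,0,0
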