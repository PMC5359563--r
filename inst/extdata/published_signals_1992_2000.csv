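"from","to","d_gain","r_gain","d_loss","r_loss"
"FL","IFL",-0.28,-0.82,0.03,1
"FL","CL",-0.13,-0.93,-0.03,-0.75
"FL","O",-1.14,-1,-0.01,-1
"FL","CoL",-0.09,-0.9,0.01,0
"FL","W",0,0,0,0
"IFL","FL",1.72,1.24,1.99,1.78
"IFL","CL",0.11,0.42,-1.47,-0.8
"IFL","O",-2.13,-1,-0.49,-0.98
"IFL","CoL",-0.1,-0.53,-0.04,-0.31
"IFL","W",0.01,0,-0.01,-0.5
"CL","FL",-1.52,-0.87,-2.31,-0.91
"CL","IFL",0.4,0.45,-2.47,-0.66
"CL","O",3.38,1.25,4.94,4.33
"CL","CoL",-0.08,-0.33,-0.13,-0.45
"CL","W",0,0,-0.04,-1
"O","FL",-0.15,-1,-0.07,-1
"O","IFL",-0.08,-1,-0.11,-1
"O","CL",-0.02,-0.67,-0.11,-0.92
"O","CoL",0.28,14,0.29,29
"O","W",0,0,0,0
"CoL","FL",-0.08,-1,-0.02,-1
"CoL","IFL",-0.01,-0.25,0,0
"CoL","CL",0.02,2,-0.01,-0.25
"CoL","O",-0.09,-0.75,0.02,2
"CoL","W",0,0,0,0
"W","FL",0.01,0.5,0.02,2
"W","IFL",0,0,-0.01,-0.5
"W","CL",0.01,0,-0.01,-0.5
"W","O",-0.02,-1,-0.01,-1
"W","CoL",0,0,0,0
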