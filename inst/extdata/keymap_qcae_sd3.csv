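instrument,item,subscale,reverse
qcae,1,cognitive_empathy,FALSE
qcae,2,cognitive_empathy,FALSE
qcae,3,cognitive_empathy,FALSE
qcae,4,cognitive_empathy,FALSE
qcae,5,cognitive_empathy,FALSE
qcae,6,cognitive_empathy,FALSE
qcae,7,cognitive_empathy,FALSE
qcae,8,cognitive_empathy,FALSE
qcae,9,cognitive_empathy,FALSE
qcae,10,cognitive_empathy,FALSE
qcae,11,cognitive_empathy,FALSE
qcae,12,cognitive_empathy,FALSE
qcae,13,cognitive_empathy,FALSE
qcae,14,cognitive_empathy,FALSE
qcae,15,cognitive_empathy,FALSE
qcae,16,cognitive_empathy,FALSE
qcae,17,cognitive_empathy,FALSE
qcae,18,cognitive_empathy,FALSE
qcae,19,cognitive_empathy,FALSE
qcae,20,affective_empathy,FALSE
qcae,21,affective_empathy,FALSE
qcae,22,affective_empathy,FALSE
qcae,23,affective_empathy,FALSE
qcae,24,affective_empathy,FALSE
qcae,25,affective_empathy,FALSE
qcae,26,affective_empathy,FALSE
qcae,27,affective_empathy,FALSE
qcae,28,affective_empathy,FALSE
qcae,29,affective_empathy,FALSE
qcae,30,affective_empathy,FALSE
qcae,31,affective_empathy,FALSE
sd3,1,machiavellianism,FALSE
sd3,2,machiavellianism,FALSE
sd3,3,machiavellianism,FALSE
sd3,4,machiavellianism,FALSE
sd3,5,machiavellianism,FALSE
sd3,6,machiavellianism,FALSE
sd3,7,machiavellianism,FALSE
sd3,8,machiavellianism,FALSE
sd3,9,machiavellianism,FALSE
sd3,10,psychopathy,FALSE
sd3,11,psychopathy,FALSE
sd3,12,psychopathy,FALSE
sd3,13,psychopathy,FALSE
sd3,14,psychopathy,FALSE
sd3,15,psychopathy,FALSE
sd3,16,psychopathy,FALSE
sd3,17,psychopathy,FALSE
sd3,18,psychopathy,FALSE
sd3,19,narcissism,FALSE
sd3,20,narcissism,FALSE
sd3,21,narcissism,FALSE
sd3,22,narcissism,FALSE
sd3,23,narcissism,FALSE
sd3,24,narcissism,FALSE
sd3,25,narcissism,FALSE
sd3,26,narcissism,FALSE
sd3,27,narcissism,FALSE
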