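word	relevant	s_rater1	s_rater2	m_rater1	m_rater2
abuse	1	1	1	0	0
shoe	1	3	3	0	0
hero	1	5	5	0	0
dementia	1	1	1	1	1
thanked	1	4	4	0	0
community	1	3	3	0	0
grateful	1	4	4	0	0
volunteer	1	3	3	0	0
long	1	3	3	0	0
celebration	1	4	4	0	0
residents	1	3	3	0	0
admired	1	4	4	0	0
teacher	1	3	3	0	0
wise	1	5	5	0	0
active	1	4	4	0	0
service	1	3	3	0	0
honoured	1	4	4	0	0
committee	1	3	3	0	0
painter	1	3	3	0	0
respected	1	5	5	0	0
award	1	4	4	0	0
everyone	1	3	3	0	0
cheered	1	4	4	0	0
smile	1	4	4	0	0
inspired	1	5	5	0	0
grand	1	4	4	0	0
nurses	1	3	3	1	1
visited	1	3	3	0	0
patients	1	2	2	1	1
new	1	3	3	0	0
clinic	1	2	3	1	1
programme	1	3	3	0	0
doctors	1	3	3	1	1
treated	1	2	2	1	1
woman	0	3	3	0	0
chronic	1	2	2	1	1
illness	1	1	1	1	1
hospital	1	2	2	1	1
comforted	1	4	4	0	0
patient	1	2	2	1	1
painful	1	1	1	1	1
sudden	1	2	2	0	0
watched	1	3	3	0	0
caregiver	1	3	3	1	0
tired	1	2	2	0	0
endure	1	2	2	0	0
sickness	1	1	1	1	1
slow	1	2	2	0	0
decline	1	1	1	1	1
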