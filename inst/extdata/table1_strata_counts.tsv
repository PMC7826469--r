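variable	stratum	event_unexposed	n_unexposed	event_exposed	n_exposed
total	total	83559	3695466	1520	28288
sex	M	28076	1274753	414	11466
sex	F	51603	2090097	776	13658
age	<40	8342	527869	60	1232
age	40-49	7758	321558	104	1998
age	50-59	13054	470547	214	4062
age	60-69	14250	472096	299	5476
age	70-100	15478	529240	248	4663
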