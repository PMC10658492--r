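id,neuter_status,age_years,breed,polydipsia,vomiting,potbelly_hepatomegaly,alopecia,pruritus,usg,alp,outcome,uccr_day1,uccr_day2,uccr_day3
d01,female_neutered,10.5,crossbreed,yes,no,yes,yes,no,dilute,elevated,case,45,38,12
d02,male_entire,8.2,Jack Russell terrier,yes,no,yes,no,no,not_recorded,elevated,case,62,55,21
d03,female_neutered,12.0,Maltese,yes,no,no,yes,no,dilute,elevated,case,28,35,30
d04,male_neutered,9.7,Beagle,yes,no,yes,no,no,not_recorded,not_recorded,case,80,74,18
d05,female_entire,11.3,Dachshund,yes,,no,no,no,dilute,elevated,noncase,8,6,5
d06,male_neutered,6.4,Labrador retriever,yes,yes,no,no,no,not_dilute,not_elevated,noncase,4,7,6
d07,female_neutered,13.1,poodle,no,no,yes,no,yes,not_recorded,not_elevated,noncase,12,9,11
d08,male_entire,10.9,French bulldog,yes,no,no,no,no,dilute,elevated,noncase,6,5,4
d09,female_neutered,7.8,Shih Tzu,yes,no,yes,yes,no,dilute,elevated,case,51,47,14
d10,male_neutered,14.2,crossbreed,yes,no,no,no,no,not_recorded,not_elevated,noncase,9,8,9
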