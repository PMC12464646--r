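category,option,rank1,rank2,rank3,rank4
high,Daily,6,3,20,
high,Every 1-2 days,12,17,0,
high,3 times a week,11,9,9,
medium,Every 1-2 days,3,3,4,19
medium,Every 2-3 days,4,11,12,2
medium,Every 2-4 days,11,8,9,1
medium,Twice a week,11,7,4,7
low,Once every working week or more frequently based on referral,19,10,0,
low,Every 3-7 days or upon referral,9,18,2,
low,Every 14 days or upon referral,1,1,27,
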