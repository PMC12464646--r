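row,statement
1,Training should include some worked examples for the model.
2,Training in how to use the prioritization tool should be available for staff new to mental health services.
3,Training should include the benefits of using the model for staff whether they are new or experienced in mental health.
4,"Clinical judgement should be incorporated in the prioritization model using a specific *other* option that pharmacy team members can select within each risk category, with a compulsory text comment field to provide any further details."
5,"The model should be introduced to staff by explaining the benefits of using the tool, previous experiences and how the model was developed."
6,The patient prioritization model should be used by both pharmacists and pharmacy technicians alike.
7,At least 1 training session should be delivered to pharmacy team members prior implementing the patient prioritization model.
8,Training should include the importance of balancing standardisation and clinical judgement when prioritizing patients.
9,Training should include some feedback from previous users of the tool.
10,Individual patients identified who have >5 amber criteria should be moved to the red category.
11,Individual patients identified who have >4 amber criteria should be moved to the red category.
12,The patient prioritization model can be used during medication reconciliation on admission.
13,Individual patients identified as low risk following completion of the prioritization model should be reviewed once every working week or more frequently based on referral.
14,Individual patients identified as high risk following completion of the prioritization model should be reviewed by or discussed with an experienced pharmacist in the relevant area.
15,Individual patients identified who have >3 amber criteria should be moved to the red category.
16,Annual training for all pharmacy teams is needed to review and update the use of the prioritization model.
17,Individual patients identified as high risk following completion of the prioritization model should be reviewed every 1-2 days.
18,Individual patients identified as medium risk following completion of the prioritization model should be reviewed twice a week.
19,Different prioritization criteria should be used by pharmacy technicians to refer patients for pharmacist review.
20,"For new admissions, staff members completing the patient prioritization model may skip the remaining criteria once they marked at least 1 red criterion. Marking 1 red criterion will identify the patient as a high-risk patient and skipping the rest of criteria will speed up the prioritization process."
21,Individual patients identified as medium risk following completion of the prioritization model should be reviewed by or discussed with an experienced pharmacist in the relevant area.
22,Individual patients identified as high risk following completion of the prioritization tool should be reviewed daily.
23,The patient prioritization tool can be used before medication reconciliation on admission.
24,Individual patients identified as medium risk following completion of the prioritization tool should be reviewed every 2-4 days.
25,Individual patients identified as high risk following completion of the prioritization tool should be reviewed 3 times a week.
26,Individual patients identified as low risk following completion of the prioritization tool should be reviewed every 3-7 days or upon referral.
27,Different prioritization criteria should be used by pharmacy technicians to categorize patients for pharmacy technician review.
28,Individual patients identified as medium risk following completion of the prioritization tool should be reviewed every 2-3 days.
29,Individual patients identified as medium risk following completion of the prioritization tool should be reviewed every 1-2 days.
30,Individual patients identified as low risk following completion of the prioritization tool should be reviewed every 14 days or upon referral.
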