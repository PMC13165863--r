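redirect_waiting: Please wait for your partner to finish
redirect_partner: Your partner is waiting. Please update them on your progress.
redirect_escalate: Please ask the researcher for help.
assist_struggling: Try asking your partner for advice.
assist_partner: Your partner seems to be struggling, please assist them.
intervene_help: Please ask the researcher for help.
auto_complete: The current step has been completed for you.
positive_step: Good job!
positive_task: Well done on working together to complete the task!
positive_together: Great job working together!
role_initiate: Try starting a conversation with your partner.
role_checkin: Try checking in with your partner.
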